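#' Build spatial-spectral-temporal (tiled) images for a trial collection
#'
#' For every trial: band-decompose, take the denoised composite, slice the
#' analysis stage, decimate, compute one Morlet scalogram per channel,
#' render each to a `tile_px` square raster and tile all sensors into one
#' composite image (ascending channel order, row-major).
#'
#' @param trials a [meg_trials()] collection.
#' @param stage stage name or time interval.
#' @param tile_px tile side in pixels.
#' @param grid tiling grid `c(rows, cols)`; default the smallest square
#'   holding all channels (14 x 14 for 196 channels).
#' @param n_freqs,decimate,omega0 scalogram parameters (see
#'   [cwt_scalogram()] and [trial_scalograms()]).
#' @return list: `images` (`H x W x 3 x N` array), `info` (trial metadata),
#'   `tile_map` (from the first trial).
#' @export
sst_images <- function(trials, stage, tile_px = 16, grid = NULL,
                       n_freqs = 64, decimate = 2, omega0 = 6) {
  nch <- length(trials$channel_ids)
  side <- ceiling(sqrt(nch))
  grid <- grid %||% c(side, side)
  n <- ncol(trials$signals[[1]])
  samples <- segment_samples(n, trials$fs, trials$t0, stage, trials$segments)
  H <- grid[1] * tile_px; W <- grid[2] * tile_px
  images <- array(0, c(H, W, 3, length(trials)))
  tile_map <- NULL
  make_image <- function(seg, ref) {
    dec <- seg[, seq(1, ncol(seg), by = decimate), drop = FALSE]
    en <- cwt_energy_multi(dec, trials$fs / decimate, n_freqs = n_freqs,
                           omega0 = omega0)
    rasters <- stats::setNames(
      render_scalogram_stack(en, c(tile_px, tile_px)), trials$channel_ids)
    tile_scalograms(rasters, grid = grid)
  }
  for (grp in trial_groups(trials)) {
    den <- dwt_bands(trials$signals[[grp[1]]])$denoised
    for (i in grp) {
      seg <- if (i == grp[1]) den[, samples, drop = FALSE] else
        shifted_segment(den, samples, trials, i)
      tiled <- make_image(seg, trials$info$id[i])
      images[, , , i] <- tiled$raster
      if (is.null(tile_map)) tile_map <- tiled$tile_map
    }
  }
  list(images = images, info = trials$info, tile_map = tile_map)
}

# group trials so each original is processed together with its augmented
# children (the denoised parent signal is decomposed once and re-windowed
# for the children); orphan children form their own singleton groups
trial_groups <- function(trials) {
  info <- trials$info
  orig <- which(is.na(info$parent_id))
  grps <- lapply(orig, function(i) {
    c(i, which(!is.na(info$parent_id) & info$parent_id == info$id[i]))
  })
  orphan <- setdiff(which(!is.na(info$parent_id)), unlist(grps))
  c(grps, as.list(orphan))
}

# slice the (possibly shifted) stage window from a denoised full-length
# trial, zero-padding past the epoch end -- the augmentation semantics
shifted_segment <- function(den, samples, trials, i) {
  shift <- trials$info$shift_ms[i]
  if (is.na(shift) || shift == 0) return(den[, samples, drop = FALSE])
  k <- round(shift / 1000 * trials$fs)
  idx <- samples + k
  seg <- matrix(0, nrow(den), length(samples))
  ok <- idx <= ncol(den)
  seg[, ok] <- den[, idx[ok], drop = FALSE]
  seg
}

#' Build per-sensor scalogram images (spectral-temporal features)
#'
#' One rendered scalogram image per (trial, channel); each image is an
#' independent training sample carrying its trial's label, and trial-level
#' decisions are recovered with [aggregate_trial()].
#'
#' @inheritParams sst_images
#' @param image_px rendered image side in pixels.
#' @return list: `images` (`image_px x image_px x 3 x (N*n_channels)`),
#'   `info` (tibble: id, trial_id, channel, label, subject).
#' @export
st_images <- function(trials, stage, image_px = 64, n_freqs = 64,
                      decimate = 2, omega0 = 6) {
  n <- ncol(trials$signals[[1]])
  samples <- segment_samples(n, trials$fs, trials$t0, stage, trials$segments)
  nch <- length(trials$channel_ids)
  images <- array(0, c(image_px, image_px, 3, length(trials) * nch))
  rows <- vector("list", length(trials))
  for (grp in trial_groups(trials)) {
    den <- dwt_bands(trials$signals[[grp[1]]])$denoised
    for (i in grp) {
      seg <- if (i == grp[1]) den[, samples, drop = FALSE] else
        shifted_segment(den, samples, trials, i)
      dec <- seg[, seq(1, ncol(seg), by = decimate), drop = FALSE]
      en <- cwt_energy_multi(dec, trials$fs / decimate, n_freqs = n_freqs,
                             omega0 = omega0)
      rasters <- render_scalogram_stack(en, c(image_px, image_px))
      for (c_i in seq_along(rasters)) {
        images[, , , (i - 1L) * nch + c_i] <- rasters[[c_i]]
      }
      rows[[i]] <- tibble(
        id = sprintf("%s_%s", trials$info$id[i], trials$channel_ids),
        trial_id = trials$info$id[i], channel = trials$channel_ids,
        label = trials$info$label[i], subject = trials$info$subject[i])
    }
  }
  list(images = images, info = bind_rows(rows))
}

#' Run the full decoding pipeline on one stage with one method
#'
#' Orchestrates preprocessing (zero-phase low-pass, optional amplitude
#' rejection), feature extraction, stratified splitting with repeats,
#' decoder training and evaluation for one analysis stage:
#'
#' * `"ann"` - six-band RMS features, shallow sigmoid ANN;
#' * `"st_cnn"` - per-sensor scalogram images pooled as samples, small CNN,
#'   trial decisions by average cross-entropy over sensors;
#' * `"sst_cnn"` - one tiled all-sensor scalogram image per trial, small
#'   CNN, with 100/200 ms time-shift augmentation of the training and
#'   validation sets (test decisions are made on original trials).
#'
#' Models are trained per subject (subject-dependent decoding) and per
#' split repeat; the report aggregates accuracy as mean and SD across
#' subjects and repeats, pools test predictions into a confusion matrix and
#' one-vs-rest AUCs, and situates accuracies against the exact binomial
#' chance level.
#'
#' @param trials a [meg_trials()] collection with labels and segment maps.
#' @param stage analysis stage name (one of the trial segment names).
#' @param method `"ann"`, `"st_cnn"` or `"sst_cnn"`.
#' @param n_repeats independent random splits (default 3).
#' @param ratios split proportions (default 70/15/15).
#' @param seed master seed for splitting and model initialisation.
#' @param lowpass apply the 250 Hz zero-phase Butterworth filter first.
#' @param reject apply [reject_trials()] with default thresholds first.
#' @param augment time-shift augmentation (default: only for `"sst_cnn"`).
#' @param shifts_ms augmentation shifts (ms).
#' @param ann_opts,cnn_opts named lists overriding [ann_config()] /
#'   [cnn_config()] defaults.
#' @param tile_px,grid,image_px,n_freqs,decimate scalogram/image geometry.
#' @param alpha significance level for the chance threshold.
#' @return object of class `eval_report`.
#' @export
run_pipeline <- function(trials, stage, method = c("ann", "st_cnn", "sst_cnn"),
                         n_repeats = 3,
                         ratios = c(train = 0.70, validation = 0.15,
                                    test = 0.15),
                         seed = 1, lowpass = TRUE, reject = FALSE,
                         augment = NULL, shifts_ms = c(100, 200),
                         ann_opts = list(), cnn_opts = list(),
                         tile_px = 16, grid = NULL, image_px = 64,
                         n_freqs = 64, decimate = 2, alpha = 0.05) {
  if (!length(trials)) abort("empty dataset: no trials to decode.")
  method <- tryCatch(match.arg(method),
                     error = function(e) abort(
                       sprintf("unknown method `%s`; valid options: ann, st_cnn, sst_cnn.",
                               method[1])))
  if (!stage %in% names(trials$segments)) {
    abort(sprintf("unknown stage `%s`; valid options: %s.", stage,
                  paste(names(trials$segments), collapse = ", ")))
  }
  augment <- augment %||% (method == "sst_cnn")
  if (lowpass) trials <- lowpass_filter(trials)
  if (reject) trials <- reject_trials(trials)$trials
  K <- length(sort(unique(trials$info$label)))
  labels <- sort(unique(trials$info$label))

  work <- if (augment) augment_shift(trials, shifts_ms) else trials
  plan <- split_data(work, ratios = ratios, n_repeats = n_repeats,
                     seed = seed)

  # features are split-independent: compute once (band sets are streamed
  # per trial inside feature_table -- holding them all would cost gigabytes
  # at full channel counts)
  if (method == "ann") {
    ft <- feature_table(work, stage, feature = "rms")
    xmat <- as.matrix(ft[, -(1:3)])
  } else if (method == "sst_cnn") {
    im <- sst_images(work, stage, tile_px = tile_px, grid = grid,
                     n_freqs = n_freqs, decimate = decimate)
  } else {
    im <- st_images(work, stage, image_px = image_px, n_freqs = n_freqs,
                    decimate = decimate)
  }

  acc_rows <- list(); pred_rows <- list()
  for (subj in sort(unique(work$info$subject))) {
    for (r in seq_len(n_repeats)) {
      asg <- plan$assignment[plan$assignment$rep == r, ]
      sets <- lapply(c(train = "train", validation = "validation",
                       test = "test"), function(s) {
        ids <- asg$id[asg$split == s]
        work$info$id %in% ids & work$info$subject == subj
      })
      # evaluate on original trials only
      test_mask <- sets$test & is.na(work$info$parent_id)
      truth <- work$info$label[test_mask]
      test_ids <- work$info$id[test_mask]

      if (method == "ann") {
        cfg <- do.call(ann_config, utils::modifyList(
          list(input_dim = ncol(xmat), n_classes = K,
               seed = seed + 1000L * r), ann_opts))
        fit <- train_ann(xmat[sets$train, , drop = FALSE],
                         work$info$label[sets$train], cfg,
                         xmat[sets$validation, , drop = FALSE],
                         work$info$label[sets$validation])
        probs <- predict(fit, xmat[test_mask, , drop = FALSE])
      } else if (method == "sst_cnn") {
        cfg <- do.call(cnn_config, utils::modifyList(
          list(input_size = dim(im$images)[1:2], n_classes = K,
               seed = seed + 1000L * r), cnn_opts))
        manifest <- dplyr::left_join(work$info[, c("id", "parent_id")],
                                     asg[, c("id", "split")], by = "id")
        fit <- train_cnn(im$images[, , , sets$train, drop = FALSE],
                         work$info$label[sets$train], cfg,
                         im$images[, , , sets$validation, drop = FALSE],
                         work$info$label[sets$validation],
                         manifest = manifest)
        probs <- predict(fit, im$images[, , , test_mask, drop = FALSE])
      } else {
        cfg <- do.call(cnn_config, utils::modifyList(
          list(input_size = dim(im$images)[1:2], n_classes = K,
               seed = seed + 1000L * r), cnn_opts))
        smap <- function(mask) im$info$trial_id %in% work$info$id[mask]
        fit <- train_cnn(im$images[, , , smap(sets$train), drop = FALSE],
                         im$info$label[smap(sets$train)], cfg,
                         im$images[, , , smap(sets$validation), drop = FALSE],
                         im$info$label[smap(sets$validation)])
        probs <- t(vapply(test_ids, function(tid) {
          sel <- im$info$trial_id == tid
          aggregate_trial(predict(fit, im$images[, , , sel, drop = FALSE]))$probs
        }, numeric(K)))
        colnames(probs) <- as.character(fit$levels)
      }

      pred <- labels[max.col(probs)]
      acc_rows[[length(acc_rows) + 1L]] <- tibble(
        subject = subj, rep = r, method = method, stage = stage,
        n_test = length(truth), accuracy = 100 * mean(pred == truth))
      pred_rows[[length(pred_rows) + 1L]] <- dplyr::bind_cols(
        tibble(subject = subj, rep = r, id = test_ids, truth = truth,
               predicted = pred),
        as_tibble(probs, .name_repair = ~ paste0("p_", labels)))
    }
  }
  accuracy <- bind_rows(acc_rows)
  predictions <- bind_rows(pred_rows)
  conf <- confusion_and_accuracy(predictions$truth, predictions$predicted,
                                 labels = labels)
  auc <- roc_auc_ovr(as.matrix(predictions[, paste0("p_", labels)]),
                     predictions$truth, labels = labels)
  chance <- chance_level(round(mean(accuracy$n_test)), K, alpha)
  vs_chance <- if (nrow(accuracy) >= 2) {
    compare_methods(accuracy$accuracy, chance = chance)
  } else NULL
  structure(
    list(stage = stage, method = method, accuracy = accuracy,
         mean_accuracy = mean(accuracy$accuracy),
         sd_accuracy = stats::sd(accuracy$accuracy),
         confusion = conf, auc = auc, chance_level = chance,
         vs_chance = vs_chance, predictions = predictions,
         settings = list(n_repeats = n_repeats, ratios = ratios,
                         seed = seed, augment = augment,
                         shifts_ms = if (augment) shifts_ms else numeric(),
                         alpha = alpha)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s @ %s: %.2f +/- %.2f %% (chance %.2f%%, macro AUC %.3f)\n",
              x$method, x$stage, x$mean_accuracy,
              ifelse(is.na(x$sd_accuracy), 0, x$sd_accuracy),
              x$chance_level, x$auc$macro_auc))
  invisible(x)
}

#' Write an evaluation report to JSON (plus TSV confusion matrix)
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(stage = report$stage, method = report$method,
              mean_accuracy = report$mean_accuracy,
              sd_accuracy = report$sd_accuracy,
              chance_level = report$chance_level,
              per_class = report$confusion$per_class,
              average_accuracy = report$confusion$average_accuracy,
              overall_accuracy = report$confusion$overall_accuracy,
              macro_auc = report$auc$macro_auc,
              accuracy = report$accuracy,
              vs_chance = report$vs_chance)
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(report$confusion$confusion,
                     file.path(dir, "confusion.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(report$auc$roc_points, file.path(dir, "roc_points.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
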
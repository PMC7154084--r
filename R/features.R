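#' RMS feature vector from a band decomposition
#'
#' Computes the root-mean-square of every (channel, band) signal over the
#' requested samples and concatenates them channel-major: for channel `c`,
#' bands delta to high-gamma. With 196 channels and six bands the vector has
#' length 1,176.
#'
#' @param bandset a [dwt_bands()] result.
#' @param samples integer sample indices of the analysis segment (use
#'   [segment_samples()] to derive them from a stage name).
#' @param channel_ids optional channel names for the feature labels.
#' @return named numeric vector of length `6 * n_channels`, names
#'   `<channel>_<band>`.
#' @export
rms_features <- function(bandset, samples, channel_ids = NULL) {
  if (!inherits(bandset, "band_set")) abort("`bandset` must be a band_set.")
  if (!length(samples)) abort("empty segment: no samples selected.")
  one <- bandset$bands[[1]]
  if (!is.matrix(one)) {
    bandset$bands <- lapply(bandset$bands, matrix, nrow = 1)
    one <- bandset$bands[[1]]
  }
  if (max(samples) > ncol(one) || min(samples) < 1) {
    abort("`samples` outside the trial extent.")
  }
  nch <- nrow(one)
  channel_ids <- channel_ids %||% sprintf("ch%03d", seq_len(nch))
  per_band <- vapply(bandset$bands, function(b) {
    sqrt(rowMeans(b[, samples, drop = FALSE]^2))
  }, numeric(nch))                       # nch x 6, column order delta..high_gamma
  per_band <- matrix(per_band, nrow = nch,
                     dimnames = list(NULL, names(bandset$bands)))
  v <- as.vector(t(per_band))            # channel-major
  names(v) <- as.vector(t(outer(channel_ids, colnames(per_band), paste, sep = "_")))
  v
}

# per-(channel, band) candidate summary statistics used in feature screening
candidate_feature_funs <- function(n_windows = 4) {
  list(
    rms = function(x) sqrt(mean(x^2)),
    mean = mean,
    median = stats::median,
    sd = stats::sd,
    quartiles = function(x) stats::quantile(x, c(0.25, 0.75), names = FALSE),
    tertiles = function(x) stats::quantile(x, c(1, 2) / 3, names = FALSE),
    energy = function(x) sum(x^2),
    windowed_energy = function(x) {
      idx <- cut(seq_along(x), n_windows, labels = FALSE)
      as.vector(tapply(x^2, idx, sum))
    })
}

#' Per-trial feature table for one analysis stage
#'
#' Runs the band decomposition on every trial (or reuses precomputed band
#' sets), extracts the requested per-(channel, band) statistic over the
#' stage segment, and returns a tibble: metadata columns `id`, `label`,
#' `subject` followed by one numeric column per feature dimension.
#'
#' @param trials a [meg_trials()] collection.
#' @param stage stage name or `c(start, end)` interval in seconds.
#' @param feature one of the candidate statistics (default `"rms"`).
#' @param bandsets optional list of precomputed [dwt_bands()] results
#'   aligned with the trials (avoids recomputation across stages).
#' @return tibble with `3 + k * 6 * n_channels` columns, where `k` is the
#'   number of values the statistic yields per signal.
#' @export
feature_table <- function(trials, stage, feature = "rms", bandsets = NULL) {
  funs <- candidate_feature_funs()
  if (!feature %in% names(funs)) {
    abort(sprintf("unknown feature `%s`; available: %s.", feature,
                  paste(names(funs), collapse = ", ")))
  }
  f <- funs[[feature]]
  n <- ncol(trials$signals[[1]])
  samples <- segment_samples(n, trials$fs, trials$t0, stage, trials$segments)
  rows <- map(seq_along(trials$signals), function(i) {
    bs <- if (is.null(bandsets)) dwt_bands(trials$signals[[i]]) else bandsets[[i]]
    vals <- lapply(names(bs$bands), function(b) {
      per_ch <- apply(bs$bands[[b]][, samples, drop = FALSE], 1, f)
      per_ch <- if (is.matrix(per_ch)) per_ch else matrix(per_ch, nrow = 1)
      # per_ch: k x nch
      lab <- if (nrow(per_ch) > 1) paste0(b, "_", seq_len(nrow(per_ch))) else b
      rownames(per_ch) <- paste0("%s_", lab)
      per_ch
    })
    k <- nrow(vals[[1]]); nch <- ncol(vals[[1]])
    ids <- trials$channel_ids
    out <- numeric(0); nm <- character(0)
    for (c_i in seq_len(nch)) {      # channel-major ordering
      for (b_i in seq_along(vals)) {
        out <- c(out, vals[[b_i]][, c_i])
        nm <- c(nm, sprintf(rownames(vals[[b_i]]), ids[c_i]))
      }
    }
    stats::setNames(out, nm)
  })
  mat <- do.call(rbind, rows)
  dplyr::bind_cols(trials$info[, c("id", "label", "subject")], as_tibble(mat))
}

#' Screen candidate feature types by class separability
#'
#' For each candidate feature table, runs a per-dimension one-way ANOVA
#' across classes followed by Tukey HSD pairwise comparisons, and summarises
#' each candidate by the fraction of dimensions whose ANOVA p-value falls
#' below `alpha`. Zero-variance (degenerate) dimensions are flagged and
#' excluded from the fraction. Candidates are ranked by that fraction.
#'
#' @param tables named list of feature matrices (`n_trials x dim`) or
#'   [feature_table()] tibbles (metadata columns are dropped automatically).
#' @param labels class labels, one per trial.
#' @param alpha significance level (default 0.001).
#' @param tukey compute Tukey HSD pairwise tests per dimension (slower).
#' @return list with `summary` (tibble: feature, n_dims, n_degenerate,
#'   frac_significant, rank) and `details` (tibble: feature, dim, p_anova,
#'   frac_pairs_significant).
#' @export
screen_features <- function(tables, labels, alpha = 0.001, tukey = TRUE) {
  if (!is.list(tables) || is.null(names(tables))) {
    abort("`tables` must be a named list of feature matrices.")
  }
  g <- factor(labels)
  if (nlevels(g) < 2) abort("feature screening needs at least 2 classes.")
  if (min(table(g)) < 3) abort("feature screening needs at least 3 trials per class.")
  details <- list()
  summary_rows <- list()
  for (nm in names(tables)) {
    m <- tables[[nm]]
    if (is.data.frame(m)) {
      m <- as.matrix(m[, setdiff(names(m), c("id", "label", "subject")), drop = FALSE])
    }
    if (nrow(m) != length(labels)) abort("feature rows must match `labels`.")
    res <- map(seq_len(ncol(m)), function(j) {
      x <- m[, j]
      if (stats::sd(x) < 1e-12 ||
          all(tapply(x, g, stats::sd) < 1e-12)) {
        return(tibble(dim = j, p_anova = NA_real_,
                      frac_pairs_significant = NA_real_, degenerate = TRUE))
      }
      fit <- stats::aov(x ~ g)
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
      fp <- if (tukey) {
        tk <- stats::TukeyHSD(fit)$g
        mean(tk[, "p adj"] < alpha)
      } else NA_real_
      tibble(dim = j, p_anova = p, frac_pairs_significant = fp,
             degenerate = FALSE)
    })
    res <- bind_rows(res)
    res$feature <- nm
    details[[nm]] <- res
    ok <- !res$degenerate
    summary_rows[[nm]] <- tibble(
      feature = nm, n_dims = ncol(m), n_degenerate = sum(!ok),
      frac_significant = if (any(ok)) mean(res$p_anova[ok] < alpha) else NA_real_)
  }
  summary <- bind_rows(summary_rows) |>
    arrange(dplyr::desc(.data$frac_significant)) |>
    mutate(rank = dplyr::row_number())
  list(summary = summary,
       details = bind_rows(details)[, c("feature", "dim", "p_anova",
                                        "frac_pairs_significant", "degenerate")])
}
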
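#' Aggregate per-sensor classifier outputs into one trial decision
#'
#' Combines the per-class probability vectors of all sensors of a trial by
#' the average cross-entropy score: for class `k` the trial score is the
#' mean over sensors of `-log p_sensor(k)`, and the predicted class
#' minimises that score (equivalently, maximises the mean log-probability,
#' the geometric-mean probability). Zero probabilities are floored at
#' `1e-12` before the log. Ties are broken towards the lowest class index
#' and flagged. `method = "mean_prob"` averages probabilities arithmetically
#' instead.
#'
#' @param probs `n_sensors x K` matrix; every row must sum to 1.
#' @param method `"mean_neglog"` (default) or `"mean_prob"`.
#' @return list with `class` (predicted column index, or column name if
#'   available), `scores` (per-class aggregate), `probs` (normalised
#'   trial-level probability vector) and `tie` flag.
#' @export
aggregate_trial <- function(probs, method = c("mean_neglog", "mean_prob")) {
  method <- match.arg(method)
  probs <- as.matrix(probs)
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    abort("every sensor's probability vector must sum to 1.")
  }
  if (method == "mean_neglog") {
    scores <- colMeans(-log(pmax(probs, 1e-12)))
    best <- min(scores)
    winners <- which(scores <= best + 1e-12)
    pv <- exp(-scores); pv <- pv / sum(pv)
  } else {
    pv <- colMeans(probs)
    scores <- -log(pmax(pv, 1e-12))
    best <- max(pv)
    winners <- which(pv >= best - 1e-12)
  }
  cls <- winners[1]
  if (!is.null(colnames(probs))) cls <- colnames(probs)[cls]
  list(class = cls, scores = scores, probs = pv, tie = length(winners) > 1)
}

#' Stratified train/validation/test split plan
#'
#' Assigns every original trial to one of the three splits, per repeat,
#' stratified by class (and by subject when present) so class proportions
#' are preserved within rounding. Augmented trials (non-missing
#' `parent_id`) inherit their parent's assignment, which prevents a trial
#' and its shifted copies from straddling splits. Deterministic under
#' `seed`.
#'
#' @param x a [meg_trials()] collection or an info tibble with columns
#'   `id`, `label` and optionally `subject`, `parent_id`.
#' @param ratios named `c(train, validation, test)` proportions summing
#'   to 1.
#' @param n_repeats number of independent random splits (default 3).
#' @param seed integer seed.
#' @return object of class `split_plan`: list with `assignment` (tibble:
#'   id, rep, split), `ratios`, `n_repeats`, `seed`.
#' @export
split_data <- function(x, ratios = c(train = 0.70, validation = 0.15,
                                     test = 0.15),
                       n_repeats = 3, seed = 1) {
  info <- if (inherits(x, "meg_trials")) x$info else as_tibble(x)
  if (abs(sum(ratios) - 1) > 1e-9) abort("`ratios` must sum to 1.")
  if (!"parent_id" %in% names(info)) info$parent_id <- NA_character_
  if (!"subject" %in% names(info)) info$subject <- 1L
  orig <- info[is.na(info$parent_id), ]
  if (!nrow(orig)) abort("no original trials to split.")
  counts <- table(orig$label)
  if (any(counts < 1)) abort("every class needs at least one trial.")
  if (any(counts < 3)) {
    warn("a class has fewer than 3 trials: it cannot be stratified across all three splits.")
  }
  splits <- names(ratios)
  assignment <- with_seed_if(seed, {
    out <- list()
    for (r in seq_len(n_repeats)) {
      strata <- split(orig$id, interaction(orig$subject, orig$label, drop = TRUE))
      for (ids in strata) {
        ids <- sample(ids)
        n <- length(ids)
        n_tr <- round(ratios[[1]] * n)
        n_va <- round(ratios[[2]] * n)
        n_te <- n - n_tr - n_va
        lab <- rep(splits, c(n_tr, n_va, max(0L, n_te)))[seq_len(n)]
        out[[length(out) + 1L]] <- tibble(id = ids, rep = r, split = lab)
      }
    }
    bind_rows(out)
  })
  kids <- info[!is.na(info$parent_id), ]
  if (nrow(kids)) {
    inherited <- dplyr::inner_join(
      kids[, c("id", "parent_id")],
      assignment, by = c(parent_id = "id"), relationship = "many-to-many")
    assignment <- bind_rows(assignment,
                            inherited[, c("id", "rep", "split")])
  }
  structure(list(assignment = arrange(assignment, .data$rep, .data$id),
                 ratios = ratios, n_repeats = n_repeats, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d repeat(s), ratios %s\n", x$n_repeats,
              paste(sprintf("%s=%.2f", names(x$ratios), x$ratios),
                    collapse = " ")))
  print(dplyr::count(x$assignment, .data$rep, .data$split))
  invisible(x)
}

#' Confusion matrix with per-class and average accuracies
#'
#' Tallies a K x K confusion matrix (rows = true class, columns =
#' predicted) and reports per-class accuracy (100 * diagonal / row sum),
#' their unweighted mean (the headline "average" accuracy) and the overall
#' trace/total accuracy.
#'
#' @param truth,predicted label vectors of equal length (non-empty).
#' @param labels class levels in display order; defaults to the sorted
#'   union of both vectors.
#' @return object of class `confusion_summary`: list with `confusion`
#'   (integer matrix), `per_class` (tibble: class, n, accuracy),
#'   `average_accuracy`, `overall_accuracy`.
#' @export
confusion_and_accuracy <- function(truth, predicted, labels = NULL) {
  if (!length(truth)) abort("empty input: no labels to score.")
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  labels <- labels %||% sort(unique(c(truth, predicted)))
  cm <- table(factor(truth, levels = labels),
              factor(predicted, levels = labels))
  cm <- matrix(as.integer(cm), nrow(cm), dimnames = dimnames(cm))
  rs <- unname(rowSums(cm))
  per_class <- tibble(
    class = labels, n = as.integer(rs),
    accuracy = ifelse(rs > 0, 100 * unname(diag(cm)) / rs, NA_real_))
  structure(
    list(confusion = cm, per_class = per_class,
         average_accuracy = mean(per_class$accuracy, na.rm = TRUE),
         overall_accuracy = 100 * sum(diag(cm)) / sum(cm)),
    class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary>\n")
  print(x$confusion)
  cat(sprintf("per-class: %s\n",
              paste(sprintf("%.2f", x$per_class$accuracy), collapse = " / ")))
  cat(sprintf("average %.2f%% | overall %.2f%%\n",
              x$average_accuracy, x$overall_accuracy))
  invisible(x)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, sweeps a threshold over that class's score column
#' (positives = trials of the class) and integrates the ROC curve by the
#' trapezoidal rule; ties in the scores are handled as in the
#' Mann-Whitney statistic. Classes absent from the truth get an `NA` AUC
#' and are flagged.
#'
#' @param scores `n x K` matrix of per-class scores (e.g. probabilities);
#'   column names, if present, must match the class labels.
#' @param truth true labels.
#' @param labels class levels aligned with the score columns.
#' @return list with `per_class` (tibble: class, auc, n_pos), `macro_auc`
#'   (mean over defined classes) and `roc_points` (tibble: class,
#'   threshold, fpr, tpr).
#' @export
roc_auc_ovr <- function(scores, truth, labels = NULL) {
  scores <- as.matrix(scores)
  labels <- labels %||% colnames(scores) %||% sort(unique(truth))
  if (length(labels) != ncol(scores)) {
    abort("`labels` must align with the score columns.")
  }
  rows <- list(); pts <- list()
  for (k in seq_along(labels)) {
    pos <- truth == labels[k]
    if (!any(pos) || all(pos)) {
      rows[[k]] <- tibble(class = labels[k], auc = NA_real_,
                          n_pos = sum(pos))
      next
    }
    s <- scores[, k]
    thr <- c(Inf, sort(unique(s), decreasing = TRUE))
    tpr <- vapply(thr, function(t) mean(s[pos] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(s[!pos] >= t), numeric(1))
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    rows[[k]] <- tibble(class = labels[k], auc = auc, n_pos = sum(pos))
    pts[[k]] <- tibble(class = labels[k], threshold = thr, fpr = fpr,
                       tpr = tpr)
  }
  per_class <- bind_rows(rows)
  if (anyNA(per_class$auc)) {
    warn("AUC undefined for class(es) absent from the truth labels.")
  }
  list(per_class = per_class,
       macro_auc = mean(per_class$auc, na.rm = TRUE),
       roc_points = bind_rows(pts))
}

#' Exact binomial chance-level accuracy
#'
#' The smallest accuracy `a` such that a random classifier (success
#' probability `1/K` per trial) reaches accuracy `>= a` with probability at
#' most `alpha`: the inverse of the exact binomial tail, reported in
#' percent. Capped at 100% when no achievable accuracy is that unlikely
#' (e.g. a single trial). Always at least `100/K`; non-increasing in the
#' number of trials.
#'
#' @param n_trials number of test trials (>= 1).
#' @param n_classes number of classes K (>= 2).
#' @param alpha significance level in (0, 1).
#' @return chance-level accuracy threshold in percent.
#' @export
chance_level <- function(n_trials, n_classes, alpha = 0.05) {
  assert_count(n_trials, "n_trials")
  if (!is_count(n_classes) || n_classes < 2) abort("`n_classes` must be >= 2.")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  p <- 1 / n_classes
  tail <- function(k) stats::pbinom(k - 1, n_trials, p, lower.tail = FALSE)
  k <- stats::qbinom(1 - alpha, n_trials, p)
  while (k <= n_trials && tail(k) > alpha) k <- k + 1
  while (k > 1 && tail(k - 1) <= alpha) k <- k - 1
  100 * min(k, n_trials) / n_trials
}

#' Compare decoding accuracies with t-tests
#'
#' Paired two-tailed t-test between two per-subject (or per-repeat)
#' accuracy arrays, or a one-sample one-tailed t-test of one array against
#' a chance-level threshold. Degenerate zero-variance inputs are flagged:
#' a zero mean difference reports p = 1, a nonzero constant difference
#' reports p = 0.
#'
#' @param a numeric accuracy vector.
#' @param b second vector (paired comparison), same length as `a`.
#' @param chance scalar chance level for the one-sample test (used when
#'   `b` is missing).
#' @return one-row tibble: comparison, statistic, df, p_value, alternative,
#'   flag.
#' @export
compare_methods <- function(a, b = NULL, chance = NULL) {
  if (is.null(b) && is.null(chance)) {
    abort("supply either `b` (paired test) or `chance` (one-sample test).")
  }
  if (!is.null(b)) {
    if (length(a) != length(b)) abort("paired arrays must have equal length.")
    if (length(a) < 2) abort("paired arrays must have length >= 2.")
    d <- a - b
    if (stats::sd(d) < 1e-12) {
      return(tibble(comparison = "paired", statistic = 0,
                    df = length(a) - 1,
                    p_value = if (abs(mean(d)) < 1e-12) 1 else 0,
                    alternative = "two.sided", flag = "zero-variance"))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    return(tibble(comparison = "paired", statistic = unname(tt$statistic),
                  df = unname(tt$parameter), p_value = tt$p.value,
                  alternative = "two.sided", flag = NA_character_))
  }
  if (length(a) < 2) abort("`a` must have length >= 2 for the one-sample test.")
  if (stats::sd(a) < 1e-12) {
    return(tibble(comparison = "vs_chance", statistic = 0,
                  df = length(a) - 1,
                  p_value = if (mean(a) > chance) 0 else 1,
                  alternative = "greater", flag = "zero-variance"))
  }
  tt <- stats::t.test(a, mu = chance, alternative = "greater")
  tibble(comparison = "vs_chance", statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         alternative = "greater", flag = NA_character_)
}

#' Pairwise method comparisons with a Holm-corrected column
#'
#' Runs [compare_methods()] on every pair of columns of a wide accuracy
#' table and reports the uncorrected p-values alongside Holm-adjusted ones
#' (the adjustment column is an extension beyond the uncorrected protocol).
#'
#' @param acc wide data frame / matrix: one column per method, one row per
#'   subject-repeat.
#' @return tibble: method_a, method_b, statistic, p_value, p_holm.
#' @export
compare_all_methods <- function(acc) {
  acc <- as.data.frame(acc)
  nm <- names(acc)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  out <- bind_rows(lapply(pairs, function(pr) {
    r <- compare_methods(acc[[pr[1]]], acc[[pr[2]]])
    tibble(method_a = pr[1], method_b = pr[2],
           statistic = r$statistic, p_value = r$p_value)
  }))
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out
}
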
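#' Time-shift data augmentation
#'
#' Creates additional labelled trials by re-windowing each trial at small
#' positive time shifts (default 100 and 200 ms), so the collection grows by
#' a factor `1 + length(shifts_ms)`. Trials store only their epoched window,
#' so the shifted child copies samples `t + shift` of its parent and
#' zero-pads the tail; the padding is noted in the augmentation log
#' (attribute `"augment_log"`). Children carry provenance (`parent_id`,
#' `shift_ms`) and inherit their parent's label, which downstream splitting
#' uses to keep a trial and its augmented versions in the same set.
#'
#' @param trials a [meg_trials()] collection of original trials.
#' @param shifts_ms positive shifts in milliseconds; empty for identity.
#' @return a [meg_trials()] collection with originals followed by children.
#' @export
augment_shift <- function(trials, shifts_ms = c(100, 200)) {
  if (!length(shifts_ms)) return(trials)
  if (any(shifts_ms <= 0)) abort("`shifts_ms` must be positive.")
  fs <- trials$fs
  signals <- trials$signals
  rows <- list(trials$info)
  log <- list()
  for (shift in shifts_ms) {
    k <- round(shift / 1000 * fs)
    for (i in seq_along(trials$signals)) {
      s <- trials$signals[[i]]
      n <- ncol(s)
      child <- matrix(0, nrow(s), n)
      if (k < n) child[, seq_len(n - k)] <- s[, (k + 1):n, drop = FALSE]
      signals[[length(signals) + 1L]] <- child
      info_row <- trials$info[i, ]
      info_row$id <- sprintf("%s_s%d", trials$info$id[i], as.integer(shift))
      info_row$parent_id <- trials$info$id[i]
      info_row$shift_ms <- shift
      rows[[length(rows) + 1L]] <- info_row
      log[[length(log) + 1L]] <- tibble(
        id = info_row$id, parent_id = trials$info$id[i], shift_ms = shift,
        zero_padded_samples = min(k, n))
    }
  }
  out <- meg_trials(signals, bind_rows(rows), fs, trials$channel_ids,
                    trials$segments, trials$t0)
  attr(out, "augment_log") <- bind_rows(log)
  out
}
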
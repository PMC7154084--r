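#' Continuous multichannel recording
#'
#' A light container for continuous data prior to epoching: a channels x
#' samples matrix, the sampling rate, channel ids and a table of stimulus
#' events (1-based sample index of stimulus onset, class label).
#'
#' @param signal numeric matrix, channels x samples.
#' @param fs sampling frequency (Hz).
#' @param channel_ids unique channel identifiers (defaults to row numbers).
#' @param events data frame with columns `sample` and `label`.
#' @return an object of class `meg_recording`.
#' @export
meg_recording <- function(signal, fs, channel_ids = NULL, events = NULL) {
  if (!is.matrix(signal)) abort("`signal` must be a channels x samples matrix.")
  assert_scalar(fs, "fs", lower = 1e-12)
  channel_ids <- channel_ids %||% sprintf("MEG%03d", seq_len(nrow(signal)))
  if (anyDuplicated(channel_ids)) abort("`channel_ids` must be unique.")
  if (length(channel_ids) != nrow(signal)) {
    abort("`channel_ids` must have one entry per signal row.")
  }
  events <- as_tibble(events %||% tibble(sample = integer(), label = integer()))
  if (!all(c("sample", "label") %in% names(events))) {
    abort("`events` must have columns `sample` and `label`.")
  }
  if (any(events$sample < 1 | events$sample > ncol(signal))) {
    abort("event sample indices must lie within the recording.")
  }
  structure(list(signal = signal, fs = fs, channel_ids = channel_ids,
                 events = events), class = "meg_recording")
}

#' Epoch a continuous recording into trials
#'
#' Cuts one fixed-length trial per stimulus event, spanning `window` seconds
#' around the event onset (default -0.5 to +4 s). Events too close to the
#' recording edges for the full window are skipped with a logged warning.
#'
#' @param rec a [meg_recording()].
#' @param window `c(start, end)` in seconds relative to each event onset.
#' @param segments stage interval map attached to the trials; defaults to the
#'   four-stage protocol map matching the window.
#' @param subject subject id stored in the trial metadata.
#' @return a [meg_trials()] collection (possibly empty).
#' @export
epoch_trials <- function(rec, window = c(-0.5, 4), segments = NULL,
                         subject = 1L) {
  if (!inherits(rec, "meg_recording")) abort("`rec` must be a meg_recording.")
  fs <- rec$fs
  n <- round((window[2] - window[1]) * fs)
  segments <- segments %||% default_segments()
  off <- round(window[1] * fs)
  signals <- list(); rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(rec$events))) {
    s0 <- rec$events$sample[i]
    lo <- s0 + off
    hi <- lo + n - 1L
    if (lo < 1L || hi > ncol(rec$signal)) {
      skipped <- skipped + 1L
      next
    }
    signals[[length(signals) + 1L]] <- rec$signal[, lo:hi, drop = FALSE]
    rows[[length(rows) + 1L]] <- tibble(
      id = sprintf("s%02d_t%04d", subject, i),
      label = rec$events$label[i], subject = subject,
      onset_sample = s0)
  }
  if (skipped > 0) {
    warn(sprintf("%d event(s) skipped: the %g-%g s window exceeds the recording bounds.",
                 skipped, window[1], window[2]))
  }
  if (!length(signals)) {
    return(meg_trials(list(), tibble(id = character(), label = integer(),
                                     subject = integer()),
                      fs, rec$channel_ids, segments, t0 = window[1]))
  }
  meg_trials(signals, bind_rows(rows), fs, rec$channel_ids, segments,
             t0 = window[1])
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass forward and backward
#' (`signal::filtfilt`), independently per channel, so segment boundaries
#' are not shifted by filter latency. The effective magnitude response is
#' the squared single-pass response.
#'
#' @param x channels x samples matrix, numeric vector, or [meg_trials()].
#' @param fs sampling frequency (Hz); taken from the object for trials.
#' @param cutoff -3 dB cutoff of the single-pass design (Hz), must be below
#'   the Nyquist frequency.
#' @param order filter order (default 4).
#' @return same shape/class as the input.
#' @export
lowpass_filter <- function(x, fs = NULL, cutoff = 250, order = 4) {
  if (inherits(x, "meg_trials")) {
    x$signals <- lapply(x$signals, lowpass_filter, fs = x$fs,
                        cutoff = cutoff, order = order)
    return(x)
  }
  if (is.null(fs)) abort("`fs` is required for matrix or vector input.")
  if (cutoff >= fs / 2) {
    abort(sprintf("cutoff %g Hz must be below the Nyquist frequency %g Hz.",
                  cutoff, fs / 2))
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  if (is.matrix(x)) {
    t(apply(x, 1, filtfilt_padded, bf = bf))
  } else {
    filtfilt_padded(x, bf)
  }
}

# forward-backward filtering with odd-reflection end padding, so the filter
# transient decays inside the padding rather than inside the trial
filtfilt_padded <- function(x, bf) {
  n <- length(x)
  p <- min(n - 1, 3 * (max(length(bf$b), length(bf$a)) - 1) * 10)
  left <- 2 * x[1] - x[(p + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(p + 1):(p + n)]
}

#' Reject trials by amplitude thresholding
#'
#' Approximates visual artifact screening: a trial is removed iff any
#' channel's peak absolute amplitude exceeds `peak_threshold`, or any
#' channel's peak-to-peak range falls below `flat_threshold` (dead channel).
#' When `peak_threshold` is `NULL` it defaults to `mad_mult` times the
#' per-channel median absolute deviation, estimated per channel across all
#' trials (robust units make the default usable on data with arbitrary
#' scale). Surviving trials are returned bit-identical.
#'
#' @param trials a [meg_trials()] collection.
#' @param peak_threshold absolute amplitude limit (scalar, or one value per
#'   channel); `NULL` for the MAD-based default.
#' @param flat_threshold minimal acceptable per-channel peak-to-peak range.
#' @param mad_mult multiplier for the MAD-based default threshold.
#' @return list with `trials` (kept) and `log`
#'   (tibble: trial_id, reason, channel, value).
#' @export
reject_trials <- function(trials, peak_threshold = NULL, flat_threshold = 0,
                          mad_mult = 6) {
  if (!is.null(peak_threshold) && any(peak_threshold <= 0)) {
    abort("`peak_threshold` must be > 0.")
  }
  if (flat_threshold < 0) abort("`flat_threshold` must be >= 0.")
  nch <- length(trials$channel_ids)
  if (is.null(peak_threshold)) {
    med_mad <- rep(0, nch)
    for (s in trials$signals) med_mad <- med_mad + apply(s, 1, stats::mad)
    peak_threshold <- mad_mult * med_mad / max(1L, length(trials$signals))
  }
  peak_threshold <- rep_len(peak_threshold, nch)
  keep <- logical(length(trials$signals))
  log <- list()
  for (i in seq_along(trials$signals)) {
    s <- trials$signals[[i]]
    peaks <- apply(abs(s), 1, max)
    p2p <- apply(s, 1, function(r) diff(range(r)))
    bad_peak <- which(peaks > peak_threshold)
    bad_flat <- which(p2p < flat_threshold)
    keep[i] <- !length(bad_peak) && !length(bad_flat)
    if (length(bad_peak)) {
      j <- bad_peak[which.max(peaks[bad_peak])]
      log[[length(log) + 1L]] <- tibble(trial_id = trials$info$id[i],
                                        reason = "peak",
                                        channel = trials$channel_ids[j],
                                        value = peaks[j])
    }
    if (length(bad_flat)) {
      j <- bad_flat[which.min(p2p[bad_flat])]
      log[[length(log) + 1L]] <- tibble(trial_id = trials$info$id[i],
                                        reason = "flat",
                                        channel = trials$channel_ids[j],
                                        value = p2p[j])
    }
  }
  log <- if (length(log)) bind_rows(log) else
    tibble(trial_id = character(), reason = character(),
           channel = character(), value = numeric())
  list(trials = trials[which(keep)], log = log)
}

#' Exclude channels from a recording or trial collection
#'
#' Removes the named channels; the ordering of the remaining channels is
#' preserved and their samples are untouched.
#'
#' @param x a [meg_recording()] or [meg_trials()].
#' @param bad_ids channel ids to drop (must all exist).
#' @return same class as `x` with the channels removed.
#' @export
exclude_channels <- function(x, bad_ids) {
  unknown <- setdiff(bad_ids, x$channel_ids)
  if (length(unknown)) {
    abort(sprintf("unknown channel id(s): %s.", paste(unknown, collapse = ", ")))
  }
  keep <- !(x$channel_ids %in% bad_ids)
  if (inherits(x, "meg_recording")) {
    x$signal <- x$signal[keep, , drop = FALSE]
  } else if (inherits(x, "meg_trials")) {
    x$signals <- lapply(x$signals, function(s) s[keep, , drop = FALSE])
  } else {
    abort("`x` must be a meg_recording or meg_trials object.")
  }
  x$channel_ids <- x$channel_ids[keep]
  x
}
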
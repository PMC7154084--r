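#' Trial collection container
#'
#' A `meg_trials` object holds a set of epoched multichannel trials: one
#' channels-by-samples matrix per trial, a tibble of per-trial metadata, and
#' shared acquisition parameters (sampling rate, channel ids, the stage
#' segment map and the epoch start time relative to stimulus onset).
#'
#' @param signals list of numeric matrices, each `n_channels x n_samples`.
#' @param info tibble with one row per trial; must contain columns `id`
#'   (unique character), `label`, `subject`. Optional columns `parent_id` and
#'   `shift_ms` record augmentation provenance (`NA` for original trials).
#' @param fs sampling frequency in Hz.
#' @param channel_ids character or integer vector naming the rows of every
#'   signal matrix.
#' @param segments named list of `c(start, end)` half-open stage intervals in
#'   seconds relative to stimulus onset, tiling the epoch.
#' @param t0 epoch start time in seconds relative to stimulus onset.
#'
#' @return An object of class `meg_trials`.
#' @export
meg_trials <- function(signals, info, fs, channel_ids, segments, t0 = NULL) {
  if (!is.list(signals)) abort("`signals` must be a list of matrices.")
  info <- as_tibble(info)
  if (nrow(info) != length(signals)) {
    abort("`info` must have one row per signal matrix.")
  }
  for (col in c("id", "label", "subject")) {
    if (!col %in% names(info)) abort(sprintf("`info` must contain column `%s`.", col))
  }
  if (anyDuplicated(info$id)) abort("trial ids must be unique.")
  if (!"parent_id" %in% names(info)) info$parent_id <- NA_character_
  if (!"shift_ms" %in% names(info)) info$shift_ms <- NA_real_
  assert_scalar(fs, "fs", lower = 1e-12)
  if (anyDuplicated(channel_ids)) abort("`channel_ids` must be unique.")
  nch <- length(channel_ids)
  for (s in signals) {
    if (!is.matrix(s) || nrow(s) != nch) {
      abort("every signal must be a matrix with one row per channel id.")
    }
  }
  t0 <- t0 %||% min(map_dbl(segments, 1))
  structure(
    list(signals = signals, info = info, fs = fs,
         channel_ids = channel_ids, segments = segments, t0 = t0),
    class = "meg_trials")
}

#' @export
length.meg_trials <- function(x) length(x$signals)

#' @export
print.meg_trials <- function(x, ...) {
  ns <- if (length(x)) ncol(x$signals[[1]]) else 0L
  cat(sprintf("<meg_trials> %d trials, %d channels x %d samples @ %g Hz\n",
              length(x), length(x$channel_ids), ns, x$fs))
  cat(sprintf("  classes: %s | subjects: %s | augmented: %d\n",
              paste(sort(unique(x$info$label)), collapse = ", "),
              paste(sort(unique(x$info$subject)), collapse = ", "),
              sum(!is.na(x$info$parent_id))))
  cat(sprintf("  epoch: [%g, %g) s; stages: %s\n", x$t0,
              x$t0 + ns / x$fs,
              paste(names(x$segments), collapse = " -> ")))
  invisible(x)
}

#' @export
`[.meg_trials` <- function(x, i) {
  idx <- seq_along(x$signals)
  names(idx) <- x$info$id
  i <- if (is.character(i)) idx[i] else idx[i]
  if (anyNA(i)) abort("unknown trial selection.")
  meg_trials(x$signals[i], x$info[i, , drop = FALSE], x$fs,
             x$channel_ids, x$segments, x$t0)
}

#' Convert a stage name or time interval to sample indices
#'
#' @param n number of samples in the epoch.
#' @param fs sampling frequency (Hz).
#' @param t0 epoch start time (s, relative to onset).
#' @param segment a stage name present in `segments`, or a numeric
#'   `c(start, end)` half-open interval in seconds.
#' @param segments named list of stage intervals.
#' @return integer vector of 1-based sample indices.
#' @export
segment_samples <- function(n, fs, t0, segment, segments = NULL) {
  if (is.character(segment)) {
    if (is.null(segments) || !segment %in% names(segments)) {
      abort(sprintf("unknown stage `%s`; available: %s.", segment,
                    paste(names(segments), collapse = ", ")))
    }
    segment <- segments[[segment]]
  }
  # half-open [start, end): first sample at or after start, last strictly before end
  lo <- floor((segment[1] - t0) * fs + 1e-9) + 1L
  hi <- ceiling((segment[2] - t0) * fs - 1e-9)
  lo <- max(1L, lo); hi <- min(n, hi)
  if (hi < lo) abort("empty segment: the interval contains no samples.")
  seq.int(lo, hi)
}

#' Write / read a trial collection
#'
#' The on-disk container is a raw little-endian float64 stream (`signals.bin`,
#' trials concatenated, each stored channel-major) plus a JSON manifest with
#' the sampling rate, channel ids, stage map and per-trial metadata.
#'
#' @param trials a `meg_trials` object.
#' @param dir directory to create/read.
#' @return `write_trials()` returns `dir` invisibly; `read_trials()` returns
#'   a `meg_trials` object.
#' @export
write_trials <- function(trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ns <- ncol(trials$signals[[1]])
  manifest <- list(
    fs = trials$fs, t0 = trials$t0,
    channel_ids = as.character(trials$channel_ids),
    n_samples = ns,
    segments = trials$segments,
    info = trials$info)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(dir, "signals.bin"), "wb")
  on.exit(close(con))
  for (s in trials$signals) writeBin(as.vector(s), con, size = 8, endian = "little")
  invisible(dir)
}

#' @rdname write_trials
#' @export
read_trials <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  nch <- length(m$channel_ids)
  ns <- m$n_samples
  ntr <- nrow(m$info)
  con <- file(file.path(dir, "signals.bin"), "rb")
  on.exit(close(con))
  signals <- vector("list", ntr)
  for (i in seq_len(ntr)) {
    signals[[i]] <- matrix(readBin(con, "double", nch * ns, size = 8,
                                   endian = "little"), nrow = nch)
  }
  segments <- lapply(m$segments, as.numeric)
  meg_trials(signals, as_tibble(m$info), m$fs, m$channel_ids, segments, m$t0)
}
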
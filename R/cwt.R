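#' Morlet continuous wavelet scalogram
#'
#' FFT-based continuous wavelet transform with an analytic Morlet mother
#' wavelet (centre frequency parameter `omega0 = 6`), evaluated at
#' log-spaced centre frequencies. The scalogram is the squared coefficient
#' magnitude per (frequency, time) cell. Input is expected to be the
#' denoised (< 125 Hz) signal; the cone of influence, derived from the
#' wavelet e-folding time, is returned as the lowest trustworthy frequency
#' per time point.
#'
#' @param x numeric vector (one channel's samples).
#' @param fs sampling frequency (Hz).
#' @param freq_range `c(low, high)` analysis range in Hz; the upper edge
#'   must be below the Nyquist frequency.
#' @param n_freqs number of log-spaced centre frequencies (default 64).
#' @param omega0 Morlet centre frequency parameter (default 6).
#' @param t0 time of the first sample (s), used for the time axis.
#' @param channel_id,trial_ref identifiers carried in the result.
#' @return object of class `scalogram`: list with `energy`
#'   (`n_freqs x n_times`, rows ordered by descending frequency),
#'   `freqs_hz`, `times_s`, `coi_hz`, `channel_id`, `trial_ref`, `params`.
#' @export
cwt_scalogram <- function(x, fs, freq_range = c(0.5, 125), n_freqs = 64,
                          omega0 = 6, t0 = 0, channel_id = NA,
                          trial_ref = NA) {
  if (freq_range[2] >= fs / 2) {
    abort(sprintf("upper analysis frequency %g Hz must be below the Nyquist frequency %g Hz.",
                  freq_range[2], fs / 2))
  }
  n <- length(x)
  freqs <- exp(seq(log(freq_range[2]), log(freq_range[1]),
                   length.out = n_freqs))          # descending
  # Fourier factor linking scale and centre frequency for the Morlet wavelet
  ff <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
  scales <- ff / freqs                             # in seconds
  M <- stats::nextn(2 * n, 2)
  X <- fft(c(x, rep(0, M - n)))
  wk <- 2 * pi * c(0:(M %/% 2), -((M - M %/% 2 - 1):1)) / M * fs  # rad/s
  pos <- wk > 0
  energy <- matrix(0, n_freqs, n)
  for (i in seq_len(n_freqs)) {
    s <- scales[i]
    psi <- numeric(M)
    psi[pos] <- pi^(-0.25) * sqrt(2 * pi * s * fs) *
      exp(-0.5 * (s * wk[pos] - omega0)^2)
    w <- fft(X * psi, inverse = TRUE)[seq_len(n)] / M
    energy[i, ] <- Mod(w)^2
  }
  tax <- t0 + (seq_len(n) - 1) / fs
  dedge <- pmin(tax - tax[1], tax[n] - tax) + 1 / fs
  coi_hz <- ff / (sqrt(2) * dedge)    # frequencies above this are edge-safe
  structure(
    list(energy = energy, freqs_hz = freqs, times_s = tax, coi_hz = coi_hz,
         channel_id = channel_id, trial_ref = trial_ref,
         params = list(wavelet = "morlet", omega0 = omega0,
                       n_freqs = n_freqs, freq_range = freq_range, fs = fs)),
    class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d freqs (%.3g-%.3g Hz) x %d times, channel %s\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              length(x$times_s), as.character(x$channel_id)))
  invisible(x)
}

# batched Morlet CWT energy: one FFT pass for all channels at once
# seg: channels x samples; returns n_freqs x n_samples x n_channels
cwt_energy_multi <- function(seg, fs, freq_range = c(0.5, 125), n_freqs = 64,
                             omega0 = 6) {
  if (freq_range[2] >= fs / 2) {
    abort(sprintf("upper analysis frequency %g Hz must be below the Nyquist frequency %g Hz.",
                  freq_range[2], fs / 2))
  }
  nch <- nrow(seg); n <- ncol(seg)
  freqs <- exp(seq(log(freq_range[2]), log(freq_range[1]),
                   length.out = n_freqs))
  ff <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
  scales <- ff / freqs
  M <- stats::nextn(2 * n, 2)
  X <- stats::mvfft(rbind(t(seg), matrix(0, M - n, nch)))
  wk <- 2 * pi * c(0:(M %/% 2), -((M - M %/% 2 - 1):1)) / M * fs
  pos <- wk > 0
  out <- array(0, c(n_freqs, n, nch))
  for (i in seq_len(n_freqs)) {
    s <- scales[i]
    psi <- numeric(M)
    psi[pos] <- pi^(-0.25) * sqrt(2 * pi * s * fs) *
      exp(-0.5 * (s * wk[pos] - omega0)^2)
    w <- stats::mvfft(X * psi, inverse = TRUE)[seq_len(n), , drop = FALSE] / M
    out[i, , ] <- Mod(w)^2
  }
  attr(out, "freqs_hz") <- freqs
  out
}

#' Per-channel scalograms for one trial segment
#'
#' Convenience wrapper: slices the denoised signal to the stage segment,
#' optionally decimates it (the denoised signal carries no content above
#' 125 Hz, so stepping down retains the full analysis band while
#' cutting the transform cost), and computes one Morlet scalogram per
#' channel.
#'
#' @param denoised channels x samples matrix (from [dwt_bands()]).
#' @param fs sampling frequency of `denoised` (Hz).
#' @param samples sample indices of the analysis segment.
#' @param decimate integer subsampling factor (default 2: 1 kHz -> 500 Hz, which keeps the full 0.5-125 Hz analysis band strictly below the Nyquist frequency).
#' @param channel_ids channel names.
#' @param trial_ref trial identifier carried into each scalogram.
#' @param freq_range,n_freqs,omega0 passed to the transform (see
#'   [cwt_scalogram()]).
#' @return named list of `scalogram` objects, one per channel.
#' @export
trial_scalograms <- function(denoised, fs, samples, decimate = 2,
                             channel_ids = NULL, trial_ref = NA,
                             freq_range = c(0.5, 125), n_freqs = 64,
                             omega0 = 6) {
  seg <- denoised[, samples, drop = FALSE]
  if (decimate > 1) {
    seg <- seg[, seq(1, ncol(seg), by = decimate), drop = FALSE]
    fs <- fs / decimate
  }
  channel_ids <- channel_ids %||% sprintf("ch%03d", seq_len(nrow(seg)))
  en <- cwt_energy_multi(seg, fs, freq_range = freq_range,
                         n_freqs = n_freqs, omega0 = omega0)
  freqs <- attr(en, "freqs_hz")
  tax <- (seq_len(ncol(seg)) - 1) / fs
  ff <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
  dedge <- pmin(tax - tax[1], tax[length(tax)] - tax) + 1 / fs
  stats::setNames(
    lapply(seq_len(nrow(seg)), function(c_i) {
      structure(
        list(energy = en[, , c_i], freqs_hz = freqs, times_s = tax,
             coi_hz = ff / (sqrt(2) * dedge),
             channel_id = channel_ids[c_i], trial_ref = trial_ref,
             params = list(wavelet = "morlet", n_freqs = length(freqs),
                           freq_range = range(freqs), fs = fs)),
        class = "scalogram")
    }),
    channel_ids)
}
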
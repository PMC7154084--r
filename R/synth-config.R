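#' Nominal neural oscillation band ranges (Hz)
#'
#' The six bands used throughout: delta 0.1-4, theta 4-8, alpha 8-16,
#' beta 16-30, gamma 31-58 and high-gamma 62-125 Hz. These are the printed
#' labels; the dyadic wavelet decomposition that realises them splits at
#' powers of two of the sampling rate (see [dwt_bands()]).
#'
#' @return named list of `c(low, high)` ranges in Hz, ordered delta to
#'   high-gamma.
#' @export
band_ranges <- function() {
  list(delta = c(0.1, 4), theta = c(4, 8), alpha = c(8, 16),
       beta = c(16, 30), gamma = c(31, 58), high_gamma = c(62, 125))
}

default_segments <- function(durations = c(pre = 0.5, perception = 1,
                                           preparation = 1, production = 2)) {
  starts <- cumsum(c(0, unname(durations)))[-(length(durations) + 1)] - durations[["pre"]]
  stats::setNames(
    lapply(seq_along(durations), function(i) c(starts[i], starts[i] + durations[[i]])),
    names(durations))
}

#' Configuration for the synthetic MEG generator
#'
#' Defines the simulated experiment: a delayed-reading protocol with four
#' stages per trial (pre-stimulus rest 0.5 s, perception 1 s, preparation
#' 1 s, production 2 s), five phrase classes with 100 trials each per
#' subject, 196 gradiometer channels sampled at 1 kHz. Class-specific
#' oscillatory signatures are injected per stage at the configured
#' signal-to-noise ratio on top of 1/f background noise.
#'
#' @param n_subjects,n_trials_per_class,n_classes,n_channels experiment counts.
#' @param fs sampling frequency (Hz).
#' @param segment_durations named numeric vector of stage durations in
#'   seconds, in protocol order starting with `pre`.
#' @param stage_snr named vector mapping stage to the linear signal-to-noise
#'   ratio, defined as RMS(class signal)/RMS(noise) over the active segment
#'   and all channels. A stage with SNR 0 receives no class signal.
#' @param noise_exponent spectral slope of the 1/f^a background, in `[0, 2]`.
#' @param noise_sd per-channel noise standard deviation (arbitrary units;
#'   0 disables noise, in which case signature amplitudes are used raw).
#' @param artifact_rate expected artifact events per trial (see
#'   [inject_artifacts()]); 0 disables artifact injection.
#' @param reaction_jitter_mean,reaction_jitter_sd mean and SD (s) of the
#'   truncated-normal reaction-time shift applied to the production-stage
#'   signature onset; truncation interval is `[0, 0.5]` s.
#' @param carryover_gain fraction (0-1) of the production-stage signal
#'   amplitude that leaks into the pre-stimulus window of the *next* stage
#'   block, emulating lingering speech processing. Default 0: the
#'   pre-stimulus window is class-independent.
#' @param edge_fraction Hann on/off ramp length as a fraction of each active
#'   segment (0 disables the envelope).
#' @param seed integer seed; a fixed seed makes generation byte-identical.
#'
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 1, n_trials_per_class = 100,
                         n_classes = 5, n_channels = 196, fs = 1000,
                         segment_durations = c(pre = 0.5, perception = 1,
                                               preparation = 1, production = 2),
                         stage_snr = c(pre = 0, perception = 0.2,
                                       preparation = 0.3, production = 0.5),
                         noise_exponent = 1, noise_sd = 1,
                         artifact_rate = 0,
                         reaction_jitter_mean = 0.25, reaction_jitter_sd = 0.1,
                         carryover_gain = 0, edge_fraction = 0.1, seed = 1) {
  for (nm in c("n_subjects", "n_trials_per_class", "n_classes", "n_channels")) {
    assert_count(get(nm), nm)
  }
  assert_scalar(fs, "fs", lower = 1e-9)
  if (is.null(names(segment_durations)) || names(segment_durations)[1] != "pre") {
    abort("`segment_durations` must be named and start with `pre`.")
  }
  if (any(segment_durations <= 0)) abort("segment durations must be > 0.")
  stages <- names(segment_durations)
  if (!setequal(names(stage_snr), stages)) {
    abort("`stage_snr` must name exactly the stages in `segment_durations`.")
  }
  if (any(stage_snr < 0)) abort("`stage_snr` values must be >= 0.")
  assert_scalar(noise_exponent, "noise_exponent", 0, 2)
  assert_scalar(noise_sd, "noise_sd", 0)
  assert_scalar(artifact_rate, "artifact_rate", 0)
  assert_scalar(carryover_gain, "carryover_gain", 0, 1)
  assert_scalar(edge_fraction, "edge_fraction", 0, 0.5)
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_trials_per_class = as.integer(n_trials_per_class),
         n_classes = as.integer(n_classes),
         n_channels = as.integer(n_channels), fs = fs,
         segment_durations = segment_durations,
         segments = default_segments(segment_durations),
         stage_snr = stage_snr[stages],
         noise_exponent = noise_exponent, noise_sd = noise_sd,
         artifact_rate = artifact_rate,
         reaction_jitter_mean = reaction_jitter_mean,
         reaction_jitter_sd = reaction_jitter_sd,
         carryover_gain = carryover_gain,
         edge_fraction = edge_fraction,
         seed = as.integer(seed)),
    class = "synth_config")
}

#' Class-specific spatio-spectral signatures
#'
#' Each class is assigned band-limited sinusoidal carriers with per-channel
#' amplitude profiles: smooth Gaussian bumps over the (abstract) channel
#' index, centred at class-specific locations, with carrier frequencies
#' strictly inside the nominal band ranges. Distinct classes always differ in
#' at least one (band, channel) amplitude. Per-class per-stage gain
#' multipliers default to 1 (the stage SNR in [synth_config()] does the
#' actual scaling).
#'
#' @param config a [synth_config()].
#' @param bands_per_class number of bands carrying each class's signature.
#' @param bands candidate band labels (subset of `names(band_ranges())`).
#' @param seed seed for the amplitude profiles; defaults to `config$seed`.
#' @return list of class `class_signatures`: one element per class, each with
#'   `bands` (named list of `list(freq, amp)`) and `stage_gains`.
#' @export
class_signatures <- function(config, bands_per_class = 2,
                             bands = c("theta", "alpha", "beta", "gamma",
                                       "high_gamma"),
                             seed = config$seed) {
  ranges <- band_ranges()
  if (!all(bands %in% names(ranges))) abort("unknown band label in `bands`.")
  K <- config$n_classes
  C <- config$n_channels
  sig <- with_seed_if(seed, {
    lapply(seq_len(K), function(k) {
      picked <- bands[((k - 1 + seq_len(bands_per_class) - 1) %% length(bands)) + 1]
      bl <- lapply(seq_along(picked), function(j) {
        b <- picked[j]
        r <- ranges[[b]]
        # carrier strictly inside the band, distinct per class
        f <- r[1] + diff(r) * (k + 0.5 * (j - 1)) / (K + 1)
        centre <- runif(1, 1, C)
        width <- max(2, C / 10)
        amp <- exp(-0.5 * ((seq_len(C) - centre) / width)^2)
        list(freq = f, amp = amp)
      })
      names(bl) <- picked
      list(bands = bl,
           stage_gains = stats::setNames(rep(1, length(config$segments)),
                                         names(config$segments)))
    })
  })
  structure(sig, class = "class_signatures")
}

validate_signatures <- function(signatures, config) {
  if (length(signatures) != config$n_classes) {
    abort(sprintf("signatures cover %d classes but the config declares %d.",
                  length(signatures), config$n_classes))
  }
  ranges <- band_ranges()
  for (k in seq_along(signatures)) {
    for (b in names(signatures[[k]]$bands)) {
      el <- signatures[[k]]$bands[[b]]
      if (el$freq >= config$fs / 2) {
        abort(sprintf("class %d %s carrier at %g Hz is not below the Nyquist frequency %g Hz.",
                      k, b, el$freq, config$fs / 2))
      }
      r <- ranges[[b]]
      if (el$freq <= r[1] || el$freq >= r[2]) {
        abort(sprintf("class %d carrier %g Hz lies outside the nominal %s band (%g-%g Hz).",
                      k, el$freq, b, r[1], r[2]))
      }
      if (length(el$amp) != config$n_channels) {
        abort("signature amplitude vectors must have one entry per channel.")
      }
    }
  }
  invisible(signatures)
}

# deterministic channels x length(idx) class signal for one stage window;
# `tsec` is the absolute time axis of the samples (s)
signature_waveform <- function(signature, tsec, edge_fraction, stage) {
  env <- hann_edges(length(tsec), edge_fraction)
  gain <- signature$stage_gains[[stage]] %||% 1
  out <- 0
  for (el in signature$bands) {
    out <- out + outer(el$amp, sin(2 * pi * el$freq * tsec) * env)
  }
  out * gain
}
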
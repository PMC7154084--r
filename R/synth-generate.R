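#' Multichannel 1/f background noise
#'
#' Gaussian noise shaped in the frequency domain so each channel's power
#' spectral density is proportional to `1/f^exponent`; channels are mutually
#' independent. Each channel is standardised to standard deviation `sd`.
#'
#' @param n_channels,n_samples output dimensions (`n_samples >= 2`).
#' @param fs sampling frequency (Hz).
#' @param exponent spectral slope in `[0, 2]`; 0 gives white noise.
#' @param seed optional integer seed for reproducibility.
#' @param sd per-channel standard deviation.
#' @return `n_channels x n_samples` matrix.
#' @export
background_noise <- function(n_channels, n_samples, fs, exponent = 1,
                             seed = NULL, sd = 1) {
  assert_count(n_channels, "n_channels")
  if (!is_count(n_samples) || n_samples < 2) abort("`n_samples` must be >= 2.")
  assert_scalar(exponent, "exponent", 0, 2)
  with_seed_if(seed, {
    w <- matrix(rnorm(n_samples * n_channels), n_samples, n_channels)
    if (exponent > 0) {
      f <- seq_len(n_samples) - 1
      f <- pmin(f, n_samples - f) * fs / n_samples   # two-sided frequency axis
      shape <- c(0, f[-1]^(-exponent / 2))           # kill DC
      w <- Re(stats::mvfft(stats::mvfft(w) * shape, inverse = TRUE)) / n_samples
    }
    w <- sweep(w, 2, colMeans(w))
    w <- sweep(w, 2, apply(w, 2, stats::sd) / sd, "/")
    t(w)
  })
}

#' Generate a labelled synthetic MEG experiment
#'
#' Builds `n_subjects x n_classes x n_trials_per_class` epoched trials. Each
#' trial is 1/f background noise plus, in every stage with a positive SNR,
#' the class's band-limited sinusoidal signature scaled so that its RMS over
#' the active segment (all channels) equals `stage_snr * noise_sd`. The
#' production-stage signature onset is delayed by a truncated-normal
#' reaction time; the pre-stimulus window receives the class signal only
#' scaled by `carryover_gain`. Label order is pseudo-randomised per subject.
#' With `noise_sd = 0` signatures are injected at their raw amplitudes,
#' which makes closed-form energy checks possible.
#'
#' @param config a [synth_config()].
#' @param signatures a [class_signatures()] set covering all classes.
#' @return a [meg_trials()] collection; `info$label` holds the ground truth
#'   (integer class 1..K).
#' @export
generate_dataset <- function(config, signatures = class_signatures(config)) {
  validate_signatures(signatures, config)
  fs <- config$fs
  segs <- config$segments
  t0 <- segs[[1]][1]
  n <- round(sum(config$segment_durations) * fs)
  tax <- t0 + (seq_len(n) - 1) / fs
  K <- config$n_classes

  with_seed_if(config$seed, {
    signals <- list()
    rows <- list()
    idx <- 0L
    for (subj in seq_len(config$n_subjects)) {
      labels <- sample(rep(seq_len(K), config$n_trials_per_class))
      for (tr in seq_along(labels)) {
        k <- labels[tr]
        x <- if (config$noise_sd > 0) {
          background_noise(config$n_channels, n, fs,
                           config$noise_exponent, sd = config$noise_sd)
        } else {
          matrix(0, config$n_channels, n)
        }
        prod_gain <- NA_real_
        for (stage in names(segs)) {
          snr <- config$stage_snr[[stage]]
          if (stage == "pre" || snr <= 0) next
          win <- segment_samples(n, fs, t0, stage, segs)
          if (stage == "production") {
            # reaction-time delay of the signature onset, truncated to [0, .5] s
            repeat {
              shift <- rnorm(1, config$reaction_jitter_mean,
                             config$reaction_jitter_sd)
              if (shift >= 0 && shift <= 0.5) break
            }
            win <- win[tax[win] >= segs[[stage]][1] + shift]
          }
          sig <- signature_waveform(signatures[[k]], tax[win],
                                    config$edge_fraction, stage)
          g <- if (config$noise_sd > 0) snr * config$noise_sd / rms(sig) else 1
          if (stage == "production") prod_gain <- g
          x[, win] <- x[, win] + g * sig
        }
        if (config$carryover_gain > 0) {
          win <- segment_samples(n, fs, t0, "pre", segs)
          sig <- signature_waveform(signatures[[k]], tax[win],
                                    config$edge_fraction, "production")
          g <- if (!is.na(prod_gain)) prod_gain else 1
          x[, win] <- x[, win] + config$carryover_gain * g * sig
        }
        idx <- idx + 1L
        signals[[idx]] <- x
        rows[[idx]] <- tibble(
          id = sprintf("s%02d_t%04d", subj, tr), label = k, subject = subj)
      }
    }
    out <- meg_trials(signals, bind_rows(rows), fs,
                      channel_ids = sprintf("MEG%03d", seq_len(config$n_channels)),
                      segments = segs, t0 = t0)
    if (config$artifact_rate > 0) {
      out <- inject_artifacts(out, config$artifact_rate)$trials
    }
    out
  })
}

#' Inject blink- and cardiac-like artifacts
#'
#' Draws a Poisson(`artifact_rate`) number of artifact events per trial.
#' Blink events are low-frequency (< 4 Hz) high-amplitude Gaussian
#' transients on a frontal channel subset; cardiac events are quasi-periodic
#' ~1 Hz trains of brief biphasic pulses on all channels. The returned log
#' records trial, time, kind and peak amplitude so rejection logic can be
#' audited.
#'
#' @param trials a [meg_trials()] collection.
#' @param artifact_rate expected events per trial (>= 0).
#' @param kinds artifact kinds to draw from (`"blink"`, `"cardiac"`).
#' @param seed optional seed.
#' @param blink_amplitude,cardiac_amplitude peak amplitudes in noise-SD units.
#' @param blink_channels channel indices receiving blinks; default the first
#'   15% of channels (abstract "frontal" subset).
#' @return list with elements `trials` (modified collection) and `log`
#'   (tibble: trial_id, time_s, kind, peak).
#' @export
inject_artifacts <- function(trials, artifact_rate, kinds = c("blink", "cardiac"),
                             seed = NULL, blink_amplitude = 15,
                             cardiac_amplitude = 3, blink_channels = NULL) {
  assert_scalar(artifact_rate, "artifact_rate", 0)
  bad <- setdiff(kinds, c("blink", "cardiac"))
  if (length(bad)) abort(sprintf("unknown artifact kind: %s.", paste(bad, collapse = ", ")))
  fs <- trials$fs
  nch <- length(trials$channel_ids)
  blink_channels <- blink_channels %||% seq_len(max(1L, round(0.15 * nch)))
  log <- list()
  if (artifact_rate > 0) {
    with_seed_if(seed, {
      for (i in seq_along(trials$signals)) {
        n <- ncol(trials$signals[[i]])
        n_ev <- rpois(1, artifact_rate)
        if (n_ev == 0) next
        for (e in seq_len(n_ev)) {
          kind <- sample(kinds, 1)
          tc <- runif(1, 0.1, n / fs - 0.1)
          tax <- (seq_len(n) - 1) / fs
          if (kind == "blink") {
            # Gaussian transient, sd 80 ms -> spectral content well below 4 Hz
            pulse <- blink_amplitude * exp(-0.5 * ((tax - tc) / 0.08)^2)
            taper <- seq(1, 0.5, length.out = length(blink_channels))
            trials$signals[[i]][blink_channels, ] <-
              trials$signals[[i]][blink_channels, ] + outer(taper, pulse)
            peak <- blink_amplitude
          } else {
            # ~1 Hz quasi-periodic biphasic pulse train across the whole trial
            period <- 1 / runif(1, 0.9, 1.2)
            centres <- seq(tc %% period, n / fs, by = period) *
              exp(rnorm(ceiling(n / fs / period + 1), 0, 0.005))[1]
            pulse <- rep(0, n)
            for (ct in centres) {
              d <- (tax - ct) / 0.02
              pulse <- pulse - cardiac_amplitude * d * exp(-0.5 * d^2) * exp(0.5)
            }
            trials$signals[[i]] <- trials$signals[[i]] +
              matrix(pulse, nch, n, byrow = TRUE)
            peak <- max(abs(pulse))
          }
          log[[length(log) + 1L]] <- tibble(
            trial_id = trials$info$id[i], time_s = tc, kind = kind, peak = peak)
        }
      }
    })
  }
  log <- if (length(log)) bind_rows(log) else
    tibble(trial_id = character(), time_s = numeric(),
           kind = character(), peak = numeric())
  list(trials = trials, log = log)
}
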
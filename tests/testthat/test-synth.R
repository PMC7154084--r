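test_that("generation is byte-identical under a fixed seed", {
  cfg <- tiny_config()
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$signals, b$signals)
  expect_identical(a$info, b$info)
  c_ <- generate_dataset(synth_config(n_trials_per_class = 4, n_classes = 3,
                                      n_channels = 8, seed = 2))
  expect_false(identical(a$signals[[1]], c_$signals[[1]]))
})

test_that("dataset geometry follows the protocol configuration", {
  cfg <- synth_config(n_subjects = 2, n_trials_per_class = 3, n_classes = 4,
                      n_channels = 6, seed = 3)
  ds <- generate_dataset(cfg)
  expect_length(ds, 2 * 3 * 4)
  expect_equal(dim(ds$signals[[1]]), c(6, 4500))
  expect_equal(ds$t0, -0.5)
  expect_setequal(unique(ds$info$label), 1:4)
  # each subject sees every class the configured number of times
  counts <- table(ds$info$subject, ds$info$label)
  expect_true(all(counts == 3))
  # pseudo-randomised label order: not simply blocked by class
  expect_false(all(ds$info$label[ds$info$subject == 1] == rep(1:4, each = 3)))
})

test_that("background noise has the configured 1/f spectral slope", {
  slope_of <- function(exponent) {
    nz <- background_noise(1, 2^14, 1000, exponent = exponent, seed = 42)
    sp <- stats::spec.pgram(nz[1, ], spans = 51, taper = 0, plot = FALSE)
    f <- sp$freq * 1000
    sel <- f >= 1 & f <= 100
    unname(stats::coef(stats::lm(log(sp$spec[sel]) ~ log(f[sel])))[2])
  }
  expect_lt(abs(slope_of(1) - (-1)), 0.15)
  expect_lt(abs(slope_of(0)), 0.15)       # white-noise limit: flat spectrum
  expect_identical(background_noise(3, 100, 1000, 1, seed = 5),
                   background_noise(3, 100, 1000, 1, seed = 5))
  expect_error(background_noise(2, 1, 1000, 1), "n_samples")
  expect_error(background_noise(2, 100, 1000, 3), "exponent")
})

test_that("injected band energy matches the closed-form sinusoid energy", {
  # noise off, no envelope, no reaction jitter: channel 5 carries a pure
  # 45 Hz carrier of amplitude 2 for the full 2 s production segment, whose
  # energy must be a^2 * T / 2; checked against an independent FFT
  # integration over the printed gamma band
  cfg <- synth_config(n_trials_per_class = 1, n_classes = 2, n_channels = 8,
                      noise_sd = 0, edge_fraction = 0,
                      reaction_jitter_mean = 0, reaction_jitter_sd = 1e-9,
                      stage_snr = c(pre = 0, perception = 0, preparation = 0,
                                    production = 1),
                      seed = 1)
  sig <- fixed_signatures(cfg)
  ds <- generate_dataset(cfg, sig)
  tr <- ds$signals[[which(ds$info$label == 1)]]
  win <- segment_samples(4500, 1000, -0.5, "production", ds$segments)
  e <- fft_band_energy(tr[5, win], 1000, 31, 58)
  expect_lt(abs(e - 2^2 * 2 / 2) / (2^2 * 2 / 2), 0.01)
  # no signal outside the carrier channel or outside production
  expect_equal(max(abs(tr[1, ])), 0)
  pre_win <- segment_samples(4500, 1000, -0.5, "pre", ds$segments)
  expect_equal(max(abs(tr[5, pre_win])), 0)
})

test_that("class signal obeys stage gating and carryover", {
  base <- list(n_trials_per_class = 1, n_classes = 2, n_channels = 8,
               noise_sd = 0, edge_fraction = 0,
               reaction_jitter_mean = 0, reaction_jitter_sd = 1e-9,
               stage_snr = c(pre = 0, perception = 0, preparation = 0,
                             production = 1),
               seed = 1)
  cfg0 <- do.call(synth_config, c(base, carryover_gain = 0))
  cfg1 <- do.call(synth_config, c(base, carryover_gain = 0.5))
  sig <- fixed_signatures(cfg0)
  pre_win <- segment_samples(4500, 1000, -0.5, "pre", cfg0$segments)
  tr0 <- generate_dataset(cfg0, sig)$signals[[1]]
  tr1 <- generate_dataset(cfg1, sig)$signals[[1]]
  expect_equal(max(abs(tr0[, pre_win])), 0)
  expect_gt(max(abs(tr1[, pre_win])), 0)
})

test_that("with all stage SNRs zero the classes are statistically indistinguishable", {
  cfg <- synth_config(n_trials_per_class = 50, n_classes = 3, n_channels = 4,
                      stage_snr = c(pre = 0, perception = 0, preparation = 0,
                                    production = 0),
                      carryover_gain = 0, seed = 9)
  ds <- generate_dataset(cfg)
  win <- segment_samples(4500, 1000, -0.5, "production", ds$segments)
  # permutation test on per-trial mean energy, one statistic per channel;
  # under the null each p is uniform, so their median must not be small
  energy <- vapply(ds$signals, function(s) rowMeans(s[, win]^2), numeric(4))
  labs <- ds$info$label
  pvals <- withr::with_seed(17, apply(energy, 1, function(e) {
    fstat <- function(l) summary(stats::aov(e ~ factor(l)))[[1]][["F value"]][1]
    obs <- fstat(labs)
    perms <- replicate(199, fstat(sample(labs)))
    mean(perms >= obs)
  }))
  expect_gt(stats::median(pvals), 0.05)
})

test_that("invalid signature or config combinations error", {
  cfg <- tiny_config()
  sig <- class_signatures(cfg)
  expect_error(generate_dataset(cfg, sig[1:2]), "classes")
  # carrier at/above Nyquist
  cfg_slow <- synth_config(n_trials_per_class = 1, n_classes = 1,
                           n_channels = 2, fs = 150, seed = 1)
  bad_sig <- structure(list(list(
    bands = list(high_gamma = list(freq = 100, amp = rep(1, 2))),
    stage_gains = c(pre = 1, perception = 1, preparation = 1, production = 1))),
    class = "class_signatures")
  expect_error(generate_dataset(cfg_slow, bad_sig), "Nyquist")
  # carrier outside its nominal band
  bad_band <- structure(list(list(
    bands = list(alpha = list(freq = 45, amp = rep(1, 8))),
    stage_gains = c(pre = 1, perception = 1, preparation = 1, production = 1))),
    class = "class_signatures")
  cfg1 <- synth_config(n_trials_per_class = 1, n_classes = 1, n_channels = 8)
  expect_error(generate_dataset(cfg1, bad_band), "nominal")
})

test_that("artifact injection matches its Poisson and amplitude contract", {
  cfg <- synth_config(n_trials_per_class = 10, n_classes = 2, n_channels = 6,
                      noise_sd = 0,
                      stage_snr = c(pre = 0, perception = 0, preparation = 0,
                                    production = 0),
                      seed = 2)
  ds <- generate_dataset(cfg)  # all-zero trials: artifacts stand alone

  none <- inject_artifacts(ds, 0)
  expect_identical(none$trials$signals, ds$signals)
  expect_equal(nrow(none$log), 0)

  rate <- 3
  res <- inject_artifacts(ds, rate, seed = 8)
  n_ev <- nrow(res$log)
  expect_lt(abs(n_ev - rate * length(ds)), 3 * sqrt(rate * length(ds)) + 1)

  blink <- inject_artifacts(ds, 2, kinds = "blink", seed = 3,
                            blink_amplitude = 15)
  hit <- unique(blink$log$trial_id)
  for (tid in hit) {
    i <- match(tid, ds$info$id)
    expect_gte(max(abs(blink$trials$signals[[i]])),
               15 * 0.999)
  }
  # blink spectral content is low-frequency: most energy below 4 Hz
  i <- match(hit[1], ds$info$id)
  ch1 <- blink$trials$signals[[i]][1, ]
  lo <- fft_band_energy(ch1, 1000, 0, 4)
  expect_gt(lo / (sum(ch1^2) / 1000), 0.9)

  expect_error(inject_artifacts(ds, 1, kinds = "saccade"), "unknown")
})
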
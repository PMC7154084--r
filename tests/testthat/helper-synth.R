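# small experiment configurations used across tests

tiny_config <- function(...) {
  synth_config(n_trials_per_class = 7, n_classes = 3, n_channels = 8,
               seed = 1, ...)
}

# deterministic two-class signature set: one carrier per class on one channel
fixed_signatures <- function(config, freqs = c(45, 10), amps = c(2, 1),
                             bands = c("gamma", "alpha"),
                             channels = c(5, 2)) {
  stages <- names(config$segments)
  sig <- lapply(seq_len(config$n_classes), function(k) {
    j <- ((k - 1) %% length(freqs)) + 1
    amp <- rep(0, config$n_channels)
    amp[channels[j]] <- amps[j]
    bl <- list(list(freq = freqs[j], amp = amp))
    names(bl) <- bands[j]
    list(bands = bl, stage_gains = stats::setNames(rep(1, length(stages)), stages))
  })
  structure(sig, class = "class_signatures")
}

# total signal energy (sum x^2 / fs) restricted to a frequency band, computed
# from the FFT independently of any wavelet code
fft_band_energy <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  sum(X[f >= lo & f <= hi]) / (n * fs)
}

# separable two-class gaussian features
gaussian_classes <- function(n_per_class, d, gap, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * d), n_per_class),
               matrix(rnorm(n_per_class * d, mean = gap), n_per_class))
    list(x = x, y = rep(1:2, each = n_per_class))
  })
}

# images with a class-dependent bright blob location, for CNN checks
blob_images <- function(n_per_class, px = 48, noise = 0.3, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    imgs <- array(0, c(px, px, 3, n))
    y <- rep(1:2, length.out = n)
    for (i in seq_len(n)) {
      ctr <- if (y[i] == 1) c(px / 4, px / 4) else c(3 * px / 4, 3 * px / 4)
      g <- outer(seq_len(px), seq_len(px), function(a, b)
        exp(-((a - ctr[1])^2 + (b - ctr[2])^2) / (px / 2)))
      for (ch in 1:3) imgs[, , ch, i] <- g + matrix(runif(px * px, 0, noise), px)
    }
    list(images = imgs, y = y)
  })
}
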
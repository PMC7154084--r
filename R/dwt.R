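# Daubechies-4 (8-tap) scaling filter, orthonormal normalisation (sums to sqrt(2))
db4_scaling <- c(
   0.230377813308855230,  0.714846570552541500,  0.630880767929590400,
  -0.027983769416983850, -0.187034811718881140,  0.030841381835986965,
   0.032883011666982945, -0.010597401784997278)

.weights_cache <- new.env(parent = emptyenv())

# Squared-magnitude frequency responses of the undecimated (MODWT) cascade
# filters for details 1..levels and the final smooth, on an M-point FFT grid.
# Columns sum to exactly 1 at every frequency (telescoping of the half-band
# identity |H|^2 + |G|^2 = 1), which is what makes the multiresolution
# analysis additively exact.
mra_weights <- function(M, levels) {
  key <- sprintf("%d_%d", M, levels)
  hit <- .weights_cache[[key]]
  if (!is.null(hit)) return(hit)
  h <- db4_scaling
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)      # wavelet (high-pass) filter via QMF
  ht <- h / sqrt(2)
  gt <- g / sqrt(2)
  w <- 2 * pi * (0:(M - 1)) / M
  resp <- function(f, stride) {
    out <- rep(0 + 0i, M)
    for (l in seq_along(f)) out <- out + f[l] * exp(-1i * w * stride * (l - 1))
    out
  }
  W <- matrix(0, M, levels + 1)
  A <- rep(1 + 0i, M)
  for (j in seq_len(levels)) {
    W[, j] <- Mod(resp(gt, 2^(j - 1)) * A)^2
    A <- resp(ht, 2^(j - 1)) * A
  }
  W[, levels + 1] <- Mod(A)^2
  colnames(W) <- c(paste0("d", seq_len(levels)), paste0("a", levels))
  .weights_cache[[key]] <- W
  W
}

#' Undecimated db4 multiresolution analysis
#'
#' Decomposes each channel into detail components `d1..d<levels>` plus the
#' final approximation `a<levels>`, all at full signal length, such that
#' their sum reproduces the input to machine precision. The transform is the
#' undecimated (maximal-overlap) analogue of the dyadic discrete wavelet
#' transform, computed in the frequency domain; signals are symmetrically
#' extended before the circular transform and trimmed afterwards to minimise
#' edge artifacts on finite epochs.
#'
#' @param x numeric vector or channels x samples matrix; length must be at
#'   least `2^levels` samples.
#' @param levels decomposition depth (default 7).
#' @return named list of components (`d1`, ..., `a<levels>`), each the same
#'   shape as `x`.
#' @export
dwt_mra <- function(x, levels = 7) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (n < 2^levels) {
    abort(sprintf("signal too short for a %d-level decomposition: %d samples given, at least %d required.",
                  levels, n, 2^levels))
  }
  # symmetric extension spanning the level-`levels` equivalent filter support
  p <- min(n, (2^levels - 1) * (length(db4_scaling) - 1))
  xpad <- cbind(x[, p:1, drop = FALSE], x, x[, n:(n - p + 1), drop = FALSE])
  M <- stats::nextn(ncol(xpad), 2)
  xpad <- cbind(xpad, matrix(0, nrow(x), M - ncol(xpad)))
  W <- mra_weights(M, levels)
  X <- stats::mvfft(t(xpad))
  keep <- p + seq_len(n)
  comps <- lapply(seq_len(levels + 1), function(j) {
    comp <- t(Re(stats::mvfft(X * W[, j], inverse = TRUE)) / M)[, keep, drop = FALSE]
    if (vec) drop(comp) else comp
  })
  stats::setNames(comps, colnames(W))
}

#' Wavelet denoising and six-band decomposition
#'
#' Runs the 7-level db4 multiresolution analysis at 1 kHz sampling and maps
#' the components to named neural oscillation bands: `d3` -> high-gamma
#' (62-125 Hz), `d4` -> gamma (31-58 Hz), `d5` -> beta (16-30 Hz), `d6` ->
#' alpha (8-16 Hz), `d7` -> theta (4-8 Hz) and `a7` -> delta (0.1-4 Hz).
#' The two finest details `d1` (250-500 Hz) and `d2` (125-250 Hz) are
#' discarded as noise; the denoised composite is the sum of the six retained
#' bands. Band labels use the conventional printed ranges; the dyadic
#' decomposition realises the corresponding power-of-two splits of the
#' sampling rate (e.g. gamma is the 31.25-62.5 Hz octave).
#'
#' @param x channels x samples matrix, numeric vector, or a [meg_trials()]
#'   trial signal.
#' @param fs sampling frequency; must be 1000 Hz (the band mapping assumes it).
#' @param wavelet only `"db4"` is implemented.
#' @param levels decomposition depth; must be 7 for the band mapping.
#' @param keep_noise if `TRUE`, the discarded `d1`/`d2` components are
#'   returned under `$noise` (used by reconstruction audits).
#' @return object of class `band_set`: list with `bands` (named list delta
#'   ... high_gamma of signals shaped like `x`), `denoised`,
#'   `nominal_ranges_hz` and `fs`.
#' @export
dwt_bands <- function(x, fs = 1000, wavelet = "db4", levels = 7,
                      keep_noise = FALSE) {
  if (!identical(wavelet, "db4")) abort("only the db4 wavelet is implemented.")
  if (fs != 1000) abort("`fs` must be 1000 Hz: the band labels assume it.")
  if (levels != 7) abort("`levels` must be 7 for the six-band mapping.")
  comps <- dwt_mra(x, levels)
  bands <- list(delta = comps$a7, theta = comps$d7, alpha = comps$d6,
                beta = comps$d5, gamma = comps$d4, high_gamma = comps$d3)
  denoised <- Reduce(`+`, bands)
  out <- list(bands = bands, denoised = denoised,
              nominal_ranges_hz = band_ranges(), fs = fs)
  if (keep_noise) out$noise <- list(d1 = comps$d1, d2 = comps$d2)
  structure(out, class = "band_set")
}

#' @export
print.band_set <- function(x, ...) {
  dims <- if (is.matrix(x$denoised)) {
    sprintf("%d channels x %d samples", nrow(x$denoised), ncol(x$denoised))
  } else {
    sprintf("%d samples", length(x$denoised))
  }
  cat(sprintf("<band_set> %s @ %g Hz; bands: %s\n", dims, x$fs,
              paste(names(x$bands), collapse = ", ")))
  invisible(x)
}
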
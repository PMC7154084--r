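#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join n
#' @importFrom purrr map map_dbl map_int imap
#' @importFrom stats fft rnorm runif rpois sd mad median quantile setNames
NULL

# run code under a fixed RNG state without disturbing the caller's stream;
# seed = NULL leaves the current stream untouched
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

assert_count <- function(x, name) {
  if (!is_count(x)) abort(sprintf("`%s` must be a single integer >= 1.", name))
  invisible(as.integer(x))
}

assert_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(as.numeric(x))
}

# Hann on/off ramps covering `frac` of the window at each edge
hann_edges <- function(n, frac = 0.1) {
  env <- rep(1, n)
  r <- floor(frac * n)
  if (r > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    env[seq_len(r)] <- ramp
    env[n + 1 - seq_len(r)] <- ramp
  }
  env
}

rms <- function(x) sqrt(mean(x^2))

# relative luminance of an RGB array (H x W x 3), linear-light approximation
raster_luminance <- function(r) {
  0.2126 * r[, , 1] + 0.7152 * r[, , 2] + 0.0722 * r[, , 3]
}
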
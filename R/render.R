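#' Render a scalogram to an RGB raster
#'
#' Energies are compressed with `log10(energy + eps)`, min-max normalised
#' per image to `[0, 1]`, bilinearly resized to the target grid, and mapped
#' through a fixed perceptually-uniform colormap (viridis). Per-image
#' normalisation follows the input conventions of image classifiers, which
#' expect each image independently scaled. A constant-energy scalogram
#' renders as a uniform single-colour raster.
#'
#' @param s a [cwt_scalogram()] result, or a plain energy matrix.
#' @param target_size `c(H, W)` output raster size in pixels (each >= 8).
#' @param eps floor added before the log; defaults to `1e-12 * max(energy)`
#'   (or 1 for an all-zero image).
#' @param palette a colormap name accepted by [grDevices::hcl.colors()].
#' @return `H x W x 3` numeric array in `[0, 1]` with attribute
#'   `render_params`.
#' @export
render_scalogram <- function(s, target_size = c(64, 64), eps = NULL,
                             palette = "viridis") {
  energy <- if (inherits(s, "scalogram")) s$energy else s
  if (any(target_size < 8)) abort("`target_size` must be at least 8 x 8.")
  mx <- max(energy)
  eps <- eps %||% if (mx > 0) 1e-12 * mx else 1
  z <- log10(energy + eps)
  rng <- range(z)
  z <- if (diff(rng) > 0) (z - rng[1]) / diff(rng) else matrix(0, nrow(z), ncol(z))
  z <- resize_bilinear(z, target_size[1], target_size[2])
  z[z < 0] <- 0; z[z > 1] <- 1
  cols <- grDevices::col2rgb(grDevices::hcl.colors(256, palette)) / 255
  idx <- pmin(255L, pmax(0L, as.integer(floor(z * 255)))) + 1L
  raster <- array(0, c(target_size[1], target_size[2], 3))
  for (ch in 1:3) raster[, , ch] <- matrix(cols[ch, idx], target_size[1])
  attr(raster, "render_params") <- list(
    scale = "log10", normalization = "minmax_per_image",
    colormap = palette, eps = eps)
  raster
}

# bilinear resize of a numeric matrix via the standard image toolkit
resize_bilinear <- function(z, h, w) {
  if (nrow(z) == h && ncol(z) == w) return(z)
  out <- EBImage::resize(z, w = h, h = w, filter = "bilinear")
  matrix(as.numeric(out), h, w)
}

# vectorised multi-image renderer: identical per-image pipeline to
# render_scalogram() (log10 + per-image min-max + bilinear resize +
# colormap), but resizing the whole frequency x time x image stack in one
# call; used by the tiled-image builders where per-call overhead matters
render_scalogram_stack <- function(stack, target_size, palette = "viridis") {
  d <- dim(stack)
  z <- array(0, d)
  for (i in seq_len(d[3])) {
    e <- stack[, , i]
    mx <- max(e)
    eps <- if (mx > 0) 1e-12 * mx else 1
    v <- log10(e + eps)
    rng <- range(v)
    z[, , i] <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else 0
  }
  z <- EBImage::resize(z, w = target_size[1], h = target_size[2],
                       filter = "bilinear")
  z <- array(as.numeric(z), c(target_size[1], target_size[2], d[3]))
  z[z < 0] <- 0; z[z > 1] <- 1
  cols <- grDevices::col2rgb(grDevices::hcl.colors(256, palette)) / 255
  idx <- array(pmin(255L, pmax(0L, as.integer(floor(z * 255)))) + 1L, dim(z))
  rasters <- lapply(seq_len(d[3]), function(i) {
    sel <- idx[, , i]
    r <- array(0, c(target_size[1], target_size[2], 3))
    for (ch in 1:3) r[, , ch] <- matrix(cols[ch, sel], target_size[1])
    attr(r, "render_params") <- list(scale = "log10",
                                     normalization = "minmax_per_image",
                                     colormap = palette)
    r
  })
  rasters
}

#' Tile per-sensor rasters into one composite image
#'
#' Places one scalogram raster per sensor into a fixed rows x cols grid,
#' row-major in the given sensor order, so a single image encodes the
#' whole-head spatial-spectral-temporal pattern. Unused cells are black.
#' The sensor-to-cell assignment is recorded in `tile_map` and
#' [extract_tile()] recovers any tile bit-exactly.
#'
#' @param rasters named list of equally-sized `h x w x 3` arrays (as from
#'   [render_scalogram()]).
#' @param grid `c(rows, cols)`; `rows * cols` must be at least the number
#'   of sensors.
#' @param order sensor ordering (default: list order). Duplicates are an
#'   error.
#' @return object of class `tiled_image`: list with `raster`
#'   (`rows*h x cols*w x 3`), `grid`, `tile_map` (tibble sensor/row/col),
#'   `tile_size`, `render_params`.
#' @export
tile_scalograms <- function(rasters, grid = c(14, 14), order = names(rasters)) {
  if (anyDuplicated(order)) abort("duplicate sensor in `order`.")
  if (!all(order %in% names(rasters))) abort("`order` names sensors not present in `rasters`.")
  ns <- length(order)
  if (ns > prod(grid)) {
    abort(sprintf("%d sensors do not fit a %d x %d grid.", ns, grid[1], grid[2]))
  }
  d <- dim(rasters[[order[1]]])
  h <- d[1]; w <- d[2]
  big <- array(0, c(grid[1] * h, grid[2] * w, 3))
  rows <- integer(ns); cols <- integer(ns)
  for (i in seq_len(ns)) {
    r <- (i - 1) %/% grid[2] + 1L
    c_ <- (i - 1) %% grid[2] + 1L
    tile <- rasters[[order[i]]]
    if (!identical(dim(tile), d)) abort("all tiles must share the same dimensions.")
    big[(r - 1) * h + seq_len(h), (c_ - 1) * w + seq_len(w), ] <- tile
    rows[i] <- r; cols[i] <- c_
  }
  structure(
    list(raster = big, grid = as.integer(grid),
         tile_map = tibble(sensor = order, row = rows, col = cols),
         tile_size = c(h, w),
         render_params = attr(rasters[[order[1]]], "render_params")),
    class = "tiled_image")
}

#' @rdname tile_scalograms
#' @param tiled a `tiled_image`.
#' @param sensor sensor id to extract.
#' @export
extract_tile <- function(tiled, sensor) {
  m <- tiled$tile_map[tiled$tile_map$sensor == sensor, ]
  if (nrow(m) != 1) abort(sprintf("sensor `%s` is not in the tile map.", sensor))
  h <- tiled$tile_size[1]; w <- tiled$tile_size[2]
  tiled$raster[(m$row - 1) * h + seq_len(h), (m$col - 1) * w + seq_len(w), ,
               drop = FALSE]
}

#' @export
print.tiled_image <- function(x, ...) {
  cat(sprintf("<tiled_image> %d x %d grid of %d x %d tiles (%d sensors), raster %d x %d x 3\n",
              x$grid[1], x$grid[2], x$tile_size[1], x$tile_size[2],
              nrow(x$tile_map), dim(x$raster)[1], dim(x$raster)[2]))
  invisible(x)
}

#' Write a raster or tiled image to PNG with a JSON sidecar
#'
#' @param x a `tiled_image` or a plain `H x W x 3` array.
#' @param path output PNG path; the sidecar is written as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_raster_png <- function(x, path) {
  if (inherits(x, "tiled_image")) {
    png::writePNG(x$raster, path)
    side <- list(grid = x$grid, tile_size = x$tile_size,
                 tile_map = x$tile_map, render_params = x$render_params)
  } else {
    png::writePNG(x, path)
    side <- list(render_params = attr(x, "render_params"))
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
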
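#' Scene stacks: time series of co-registered reflectance scenes
#'
#' A `scene_stack` holds a time-ordered set of multiband reflectance scenes
#' sharing one grid: acquisition `dates`, per-pixel `red` and `nir`
#' reflectance matrices (pixels x scenes), a logical `valid` matrix of
#' per-pixel-per-scene quality flags (cloud mask), and the pixel index.
#' Statistics in this package only ever use valid observations.
#'
#' @param dates Date vector, one per scene, strictly increasing.
#' @param red,nir Numeric matrices, `n_pixels x n_scenes`.
#' @param valid Logical matrix, same shape.
#' @param pixel_index Tibble with `row`, `col` for each matrix row.
#' @param cell_size Cell edge length, m.
#' @return An object of class `scene_stack`.
#' @export
scene_stack <- function(dates, red, nir, valid, pixel_index, cell_size = 30) {
  dates <- as.Date(dates)
  stopifnot(
    !is.unsorted(dates, strictly = TRUE),
    is.matrix(red), is.matrix(nir), is.matrix(valid),
    all(dim(red) == dim(nir)), all(dim(red) == dim(valid)),
    ncol(red) == length(dates),
    nrow(red) == nrow(pixel_index)
  )
  structure(
    list(dates = dates, red = red, nir = nir, valid = valid,
         pixel_index = tibble::as_tibble(pixel_index), cell_size = cell_size),
    class = "scene_stack"
  )
}

#' @export
print.scene_stack <- function(x, ...) {
  cat("<scene_stack> ", nrow(x$red), " pixels x ", length(x$dates),
      " scenes (", format(min(x$dates)), " .. ", format(max(x$dates)),
      "), ", round(100 * mean(x$valid), 1), "% valid\n", sep = "")
  invisible(x)
}

#' @export
#' @method as_tibble scene_stack
#' @rdname scene_stack
#' @param x A `scene_stack`.
#' @param ... Unused.
as_tibble.scene_stack <- function(x, ...) {
  n_px <- nrow(x$red)
  n_sc <- length(x$dates)
  tibble::tibble(
    row = rep(x$pixel_index$row, times = n_sc),
    col = rep(x$pixel_index$col, times = n_sc),
    date = rep(x$dates, each = n_px),
    red = as.vector(x$red),
    nir = as.vector(x$nir),
    valid = as.vector(x$valid)
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

# column selector for a date window [from, to], inclusive
window_cols <- function(stack, window) {
  stopifnot(length(window) == 2L)
  from <- as.Date(window[[1]])
  to <- as.Date(window[[2]])
  which(stack$dates >= from & stack$dates <= to)
}

#' Per-scene NDVI matrix of a stack
#'
#' @param stack A [scene_stack()].
#' @return Numeric matrix (pixels x scenes) of NDVI values.
#' @export
ndvi_matrix <- function(stack) {
  stopifnot(inherits(stack, "scene_stack"))
  ndvi(stack$nir, stack$red)
}

#' Generate a synthetic reflectance time series
#'
#' Builds the red/NIR scene stack realizing each pixel's NDVI trajectory:
#' stationary around `ndvi_ref_true` before the storm; an instantaneous
#' class-dependent drop `ndvi_drop_true` at the storm date; then linear
#' change at `recovery_rate_true` NDVI/yr, capped at full recovery (ponded
#' pixels keep browning, floored at NDVI 0.05). Gaussian noise with sd
#' `noise_sd_reflectance` is added on the NDVI scale and reflectances are
#' back-computed holding NIR at 0.4, so index recomputation from the bands
#' is exact. Each scene's valid mask is an independent
#' Bernoulli(1 - `cloud_prob`) draw per pixel.
#'
#' @param config A [landscape_config()].
#' @param pixels Pixel tibble from [generate_canopy()].
#' @return A [scene_stack()].
#' @export
generate_reflectance_series <- function(config, pixels) {
  stopifnot(inherits(config, "landscape_config"))
  need <- c("ndvi_ref_true", "ndvi_drop_true", "recovery_rate_true")
  if (!all(need %in% names(pixels))) {
    stop("pixels must come from generate_canopy()")
  }
  withr::with_seed(stage_seed(config$seed, "scenes"), {
    dates <- seq(config$series_start, config$series_end,
                 by = paste(config$revisit_days, "days"))
    n_px <- nrow(pixels)
    n_sc <- length(dates)
    dt_yr <- as.numeric(dates - config$storm_date) / 365.25 # years since storm

    ref <- pixels$ndvi_ref_true
    drop <- pixels$ndvi_drop_true
    rate <- pixels$recovery_rate_true

    v <- matrix(ref, n_px, n_sc)
    post <- which(dt_yr >= 0)
    if (length(post)) {
      elapsed <- matrix(dt_yr[post], n_px, length(post), byrow = TRUE)
      recovering <- rate > 0
      deficit <- matrix(drop, n_px, length(post)) - rate * elapsed
      deficit[recovering, ] <- pmax(deficit[recovering, , drop = FALSE], 0)
      vpost <- matrix(ref, n_px, length(post)) - deficit
      vpost[!recovering, ] <- pmax(vpost[!recovering, , drop = FALSE], 0.05)
      v[, post] <- vpost
    }
    v <- v + matrix(rnorm(n_px * n_sc, sd = config$noise_sd_reflectance),
                    n_px, n_sc)
    v <- pmin(pmax(v, -0.99), 0.99)

    nir <- matrix(0.4, n_px, n_sc)
    red <- nir * (1 - v) / (1 + v)
    valid <- matrix(runif(n_px * n_sc) >= config$cloud_prob, n_px, n_sc)

    scene_stack(dates, red, nir, valid,
                pixel_index = pixels[, c("row", "col")],
                cell_size = config$cell_size)
  })
}

#' Simulate a complete synthetic landscape
#'
#' Runs the full generator chain (terrain, storm fields, canopy and truth,
#' reflectance series) under one configuration.
#'
#' @param config A [landscape_config()].
#' @return A list of class `storm_landscape` with elements `pixels` (tibble,
#'   one row per grid cell with all static layers and ground truth), `scenes`
#'   (a [scene_stack()]) and `config`.
#' @examples
#' ls <- simulate_landscape(landscape_config(grid_rows = 25, grid_cols = 25,
#'                                           revisit_days = 48))
#' dplyr::count(ls$pixels, true_resilience)
#' @export
simulate_landscape <- function(config = landscape_config()) {
  pixels <- generate_terrain(config)
  pixels <- generate_storm_fields(config, pixels)
  pixels <- generate_canopy(config, pixels)
  scenes <- generate_reflectance_series(config, pixels)
  structure(list(pixels = pixels, scenes = scenes, config = config),
            class = "storm_landscape")
}

#' @export
print.storm_landscape <- function(x, ...) {
  cat("<storm_landscape> ", x$config$grid_rows, "x", x$config$grid_cols,
      " grid, ", sum(x$pixels$mangrove), " mangrove pixels\n", sep = "")
  print(x$scenes)
  invisible(x)
}
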
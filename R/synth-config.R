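#' Configuration for the synthetic coastal landscape generator
#'
#' Bundles every knob of the synthetic landscape: grid geometry, the storm and
#' observation calendar, the hydrology that drives dieback (basin fraction,
#' berm height, surge amplitude), wind exposure, reflectance noise and the
#' post-storm NDVI recovery rates. One master `seed` governs all stochastic
#' draws; every generator stage derives its own stream from it, so identical
#' configurations reproduce identical landscapes bit for bit.
#'
#' The defaults emulate the structure of a hurricane-struck mangrove coast:
#' a 200 x 200 grid of 30 m cells (Landsat-like), ~30% of the terrain in
#' low-lying endorheic basins (3-16 cm asl) enclosed by a ~0.5 m berm, a ~3 m
#' storm surge decaying inland, maximum winds spanning 26-55 m/s, a 16-day
#' revisit with 30% cloud cover, and linear post-storm NDVI recovery: fast
#' (`recovery_rate_drained`, resprouting within roughly a year) on drained
#' sites, negative (`recovery_rate_ponded`, continued browning) on ponded
#' sites. Storm-time NDVI drops are drawn per ground-truth resilience class
#' from `drop_high`, `drop_intermediate` and `drop_low`.
#'
#' @param grid_rows,grid_cols Grid dimensions (pixels).
#' @param cell_size Cell edge length, m.
#' @param seed Master integer seed.
#' @param basin_fraction Fraction of the grid carved into ponded interior
#'   basins, in `[0, 1]`.
#' @param berm_height Height of the enclosing berm crest, m asl.
#' @param surge_amplitude Peak storm-surge water-surface elevation at the
#'   coast, m asl.
#' @param wind_range Length-2 numeric, min and max of the maximum-wind
#'   gradient, m/s.
#' @param storm_date,series_start,series_end Dates (coercible via
#'   [as.Date()]); `series_start < storm_date < series_end`.
#' @param revisit_days Days between successive scenes (>= 1).
#' @param cloud_prob Per-pixel-per-scene probability of an invalid (cloudy)
#'   observation, in `[0, 1)`.
#' @param noise_sd_reflectance Gaussian noise sd applied on the NDVI scale
#'   before reflectances are back-computed.
#' @param recovery_rate_drained Post-storm NDVI slope on drained,
#'   high-resilience pixels, NDVI/yr.
#' @param recovery_rate_ponded Post-storm NDVI slope on ponded pixels,
#'   NDVI/yr (<= 0: failed recovery).
#' @param intermediate_fraction Share of drained mangrove pixels assigned the
#'   intermediate ground-truth class (slow, 6-13 yr predicted recovery).
#' @param drop_high,drop_intermediate,drop_low Length-2 ranges of the
#'   storm-time NDVI drop for the three ground-truth classes.
#' @param dsm_intercept,dsm_slope,dsm_noise_sd True parameters of the linear
#'   lidar-to-stereo-DSM relation `dsm = a + b * chm + N(0, sd)`, used to test
#'   bias-correction recovery.
#' @return A validated list of class `landscape_config`.
#' @examples
#' cfg <- landscape_config(grid_rows = 40, grid_cols = 40, seed = 1)
#' cfg$basin_fraction
#' @export
landscape_config <- function(grid_rows = 200, grid_cols = 200, cell_size = 30,
                             seed = 42,
                             basin_fraction = 0.30, berm_height = 0.5,
                             surge_amplitude = 3.0, wind_range = c(26, 55),
                             storm_date = "2017-09-10",
                             series_start = "2015-08-31",
                             series_end = "2018-12-31",
                             revisit_days = 16, cloud_prob = 0.30,
                             noise_sd_reflectance = 0.02,
                             recovery_rate_drained = 0.30,
                             recovery_rate_ponded = -0.05,
                             intermediate_fraction = 0.25,
                             drop_high = c(0.02, 0.08),
                             drop_intermediate = c(0.12, 0.19),
                             drop_low = c(0.25, 0.40),
                             dsm_intercept = 2.0, dsm_slope = 0.9,
                             dsm_noise_sd = 0.1) {
  if (grid_rows <= 0 || grid_cols <= 0) {
    stop("grid dimensions must be positive")
  }
  stopifnot(
    cell_size > 0,
    basin_fraction >= 0, basin_fraction <= 1,
    cloud_prob >= 0, cloud_prob < 1,
    revisit_days >= 1,
    length(wind_range) == 2L, wind_range[1] < wind_range[2],
    intermediate_fraction >= 0, intermediate_fraction <= 1
  )
  storm_date <- as.Date(storm_date)
  series_start <- as.Date(series_start)
  series_end <- as.Date(series_end)
  stopifnot(is_date_scalar(storm_date), is_date_scalar(series_start),
            is_date_scalar(series_end))
  if (!(series_start < storm_date && storm_date < series_end)) {
    stop("need series_start < storm_date < series_end")
  }
  for (rng in list(drop_high, drop_intermediate, drop_low)) {
    stopifnot(length(rng) == 2L, rng[1] <= rng[2])
  }
  structure(
    list(
      grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
      cell_size = cell_size, seed = as.integer(seed),
      basin_fraction = basin_fraction, berm_height = berm_height,
      surge_amplitude = surge_amplitude, wind_range = as.numeric(wind_range),
      storm_date = storm_date, series_start = series_start,
      series_end = series_end, revisit_days = revisit_days,
      cloud_prob = cloud_prob, noise_sd_reflectance = noise_sd_reflectance,
      recovery_rate_drained = recovery_rate_drained,
      recovery_rate_ponded = recovery_rate_ponded,
      intermediate_fraction = intermediate_fraction,
      drop_high = drop_high, drop_intermediate = drop_intermediate,
      drop_low = drop_low,
      dsm_intercept = dsm_intercept, dsm_slope = dsm_slope,
      dsm_noise_sd = dsm_noise_sd
    ),
    class = "landscape_config"
  )
}

#' @export
print.landscape_config <- function(x, ...) {
  cat("<landscape_config> ", x$grid_rows, "x", x$grid_cols, " grid @ ",
      x$cell_size, " m, seed ", x$seed, "\n", sep = "")
  cat("  basins: ", round(100 * x$basin_fraction), "% of terrain, berm ",
      x$berm_height, " m; surge ", x$surge_amplitude, " m; winds ",
      x$wind_range[1], "-", x$wind_range[2], " m/s\n", sep = "")
  cat("  series ", format(x$series_start), " .. ", format(x$series_end),
      ", storm ", format(x$storm_date), ", revisit ", x$revisit_days,
      " d, cloud p ", x$cloud_prob, "\n", sep = "")
  invisible(x)
}

#' Species labels used by the synthetic landscape
#'
#' Dominant-community labels: the salt-tolerant basin specialist
#' *Avicennia germinans*, the fringe species *Rhizophora mangle*,
#' *Laguncularia racemosa*, the high-ground *Conocarpus erectus*, and mixed
#' stands.
#' @return Character vector of the five labels.
#' @export
species_levels <- function() {
  c("A. germinans", "R. mangle", "L. racemosa", "C. erectus", "mixed")
}

#' Resilience class labels, worst to best
#' @return `c("low", "intermediate", "high")`.
#' @export
resilience_levels <- function() c("low", "intermediate", "high")
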
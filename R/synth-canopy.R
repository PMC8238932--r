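#' Generate canopy structure, storm damage and ground-truth labels
#'
#' Adds the vegetation-structure layers and the ground truth the validation
#' suite scores against:
#'
#' * `chm_pre`: pre-storm canopy height, taller in drained (riverine/fringe)
#'   zones, shorter scrub in ponded basins;
#' * `true_height_loss`: wind damage increasing with pre-storm height and
#'   weakly with wind exposure; `chm_post = chm_pre - loss >= 0`;
#' * `dsm_pre`: a stereo surface model linearly related to the lidar canopy
#'   height (`dsm = a + b * chm + noise`, with `(a, b)` from the config), for
#'   exercising bias-correction recovery;
#' * `fvc_pre`/`fvc_post`: lidar fractional vegetation cover in `[0, 1]`,
#'   with storm defoliation strongest on ponded dieback pixels
#'   (`fvc_post <= fvc_pre`), plus their five-class bins;
#' * `true_resilience`: the ground-truth class. Ponded mangrove pixels are
#'   `low` (dieback); drained mangrove pixels split into `high` (small NDVI
#'   drop, fast recovery) and `intermediate` (moderate drop, slow recovery)
#'   with spatially coherent patches;
#' * the per-pixel NDVI trajectory parameters consumed by
#'   [generate_reflectance_series()]: `ndvi_ref_true`, `ndvi_drop_true`,
#'   `recovery_rate_true`.
#'
#' @param config A [landscape_config()].
#' @param pixels Pixel tibble from [generate_storm_fields()].
#' @return `pixels` with the canopy, cover and truth columns appended.
#' @export
generate_canopy <- function(config, pixels) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$grid_rows
  nc <- config$grid_cols
  if (!all(c("drainage", "max_wind", "mangrove") %in% names(pixels))) {
    stop("pixels must come from generate_storm_fields()")
  }
  withr::with_seed(stage_seed(config$seed, "canopy"), {
    n <- nrow(pixels)
    ponded <- pixels$drainage == "ponded"

    # canopy height: smooth stand-structure field, taller where drained
    h_field <- (as.vector(smooth_field(nr, nc, range = max(3, nr %/% 16))) + 2.5) / 5
    h_field <- pmin(pmax(h_field, 0), 1)
    chm_pre <- ifelse(ponded,
                      2.0 + 12 * h_field,
                      3.0 + 18 * h_field^1.2) + rnorm(n, sd = 0.5)
    chm_pre <- pmax(chm_pre, 0.2)
    chm_pre[!pixels$mangrove] <- pmax(chm_pre[!pixels$mangrove] * 0.6, 0.2)

    # height loss: proportional to pre-storm height, increasing in wind
    wind_norm <- (pixels$max_wind - config$wind_range[1]) /
      diff(config$wind_range)
    loss_frac <- 0.10 + 0.08 * wind_norm + 0.04 * runif(n)
    true_height_loss <- pmin(chm_pre * loss_frac, chm_pre)
    true_height_loss[chm_pre <= 0] <- 0
    chm_post <- chm_pre - true_height_loss

    # stereo DSM linearly biased against lidar height
    dsm_pre <- config$dsm_intercept + config$dsm_slope * chm_pre +
      rnorm(n, sd = config$dsm_noise_sd)

    # ground-truth resilience: ponded -> low; drained mangroves split into
    # intermediate patches and high elsewhere
    int_field <- as.vector(smooth_field(nr, nc, range = max(3, nr %/% 18)))
    true_resilience <- rep(NA_character_, n)
    true_resilience[pixels$mangrove & ponded] <- "low"
    drained_m <- pixels$mangrove & !ponded
    if (any(drained_m) && config$intermediate_fraction > 0) {
      cut <- quantile(int_field[drained_m],
                      probs = config$intermediate_fraction)
      true_resilience[drained_m] <-
        ifelse(int_field[drained_m] <= cut, "intermediate", "high")
    } else {
      true_resilience[drained_m] <- "high"
    }
    true_resilience <- factor(true_resilience, levels = resilience_levels())

    # storm-time NDVI drop and linear recovery rate per truth class.
    # Intermediate pixels draw a per-pixel rate targeting a 6-13 yr predicted
    # recovery; high pixels resprout at the fast drained rate; ponded pixels
    # keep browning at the (non-positive) ponded rate.
    ndvi_drop_true <- runif(n, config$drop_high[1], config$drop_high[2])
    idx_int <- which(!is.na(true_resilience) & true_resilience == "intermediate")
    idx_low <- which(!is.na(true_resilience) & true_resilience == "low")
    ndvi_drop_true[idx_int] <- runif(length(idx_int),
                                     config$drop_intermediate[1],
                                     config$drop_intermediate[2])
    ndvi_drop_true[idx_low] <- runif(length(idx_low),
                                     config$drop_low[1], config$drop_low[2])
    recovery_rate_true <- rep(config$recovery_rate_drained, n)
    target_years <- runif(length(idx_int), 7, 13)
    recovery_rate_true[idx_int] <- ndvi_drop_true[idx_int] / target_years
    recovery_rate_true[idx_low] <- config$recovery_rate_ponded
    # non-mangrove ground: mild, fast-recovering disturbance
    recovery_rate_true[!pixels$mangrove] <- config$recovery_rate_drained

    # fractional vegetation cover tied to canopy height; pre-storm NDVI
    # tied to cover through a linear greenness relation
    fvc_pre <- 0.15 + 0.95 * (1 - exp(-chm_pre / 7)) + rnorm(n, sd = 0.06)
    fvc_pre <- pmin(pmax(fvc_pre, 0.02), 1)
    ndvi_ref_true <- 0.35 + 0.55 * fvc_pre + rnorm(n, sd = 0.01)
    ndvi_ref_true <- pmin(pmax(ndvi_ref_true, 0.2), 0.92)

    # storm defoliation realizes the NDVI drop through the same greenness
    # relation, so post-storm reflectance encodes post-storm cover; clamped
    # where the drop exceeds what the standing cover allows
    defol <- pmin(ndvi_drop_true / (0.55 * pmax(fvc_pre, 0.05)), 0.95)
    fvc_post <- pmin(fvc_pre * (1 - defol), fvc_pre)

    bins <- fvc_class_bins()
    dplyr::mutate(
      pixels,
      chm_pre = chm_pre, chm_post = chm_post,
      true_height_loss = true_height_loss,
      dsm_pre = dsm_pre,
      fvc_pre = fvc_pre, fvc_post = fvc_post,
      true_fvc_class_pre = bin_values(fvc_pre, bins),
      true_fvc_class_post = bin_values(fvc_post, bins),
      true_resilience = true_resilience,
      ndvi_ref_true = ndvi_ref_true,
      ndvi_drop_true = ndvi_drop_true,
      recovery_rate_true = recovery_rate_true
    )
  })
}
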
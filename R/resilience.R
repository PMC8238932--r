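#' Normalized difference indices
#'
#' `ndvi()` computes the Normalized Difference Vegetation Index
#' `(nir - red) / (nir + red)`; `ndwi()` the Normalized Difference Water
#' Index `(green - nir) / (green + nir)`. Results are clipped to `[-1, 1]`;
#' a zero denominator yields `NA`.
#'
#' @param nir,red,green Reflectance values (vectors or matrices of the same
#'   shape).
#' @return Index values in `[-1, 1]`, same shape as the inputs.
#' @examples
#' ndvi(0.4, 0.1)
#' @export
ndvi <- function(nir, red) {
  den <- nir + red
  out <- (nir - red) / den
  out[!is.na(den) & den == 0] <- NA
  pmin(pmax(out, -1), 1)
}

#' @rdname ndvi
#' @export
ndwi <- function(green, nir) {
  den <- green + nir
  out <- (green - nir) / den
  out[!is.na(den) & den == 0] <- NA
  pmin(pmax(out, -1), 1)
}

#' Compositing and classification windows
#'
#' The analysis calendar: a two-year pre-storm reference window, the
#' immediate post-storm window used for the post-storm composite, the
#' 15-month anomaly-accumulation window, and the recovery-slope window
#' (the first full calendar year after the storm, so the immediate
#' post-storm months of delayed browning are excluded from the slope fit).
#' Defaults correspond to a 10 September 2017 storm.
#'
#' @param pre_window,post_window,anomaly_window,slope_window Length-2 date
#'   pairs (coercible via [as.Date()]).
#' @return A list of class `composite_config`.
#' @export
composite_config <- function(pre_window = c("2015-08-31", "2017-08-31"),
                             post_window = c("2017-10-01", "2017-12-31"),
                             anomaly_window = c("2017-09-17", "2018-12-31"),
                             slope_window = c("2018-01-01", "2018-12-31")) {
  as_win <- function(w, nm) {
    w <- tryCatch(as.Date(w), error = function(e) as.Date(NA))
    if (length(w) != 2L || anyNA(w) || w[1] > w[2]) {
      stop("invalid date window: ", nm)
    }
    w
  }
  cfg <- list(
    pre_window = as_win(pre_window, "pre_window"),
    post_window = as_win(post_window, "post_window"),
    anomaly_window = as_win(anomaly_window, "anomaly_window"),
    slope_window = as_win(slope_window, "slope_window")
  )
  if (cfg$pre_window[2] > cfg$post_window[1]) {
    stop("pre_window must end before post_window begins")
  }
  structure(cfg, class = "composite_config")
}

#' Thresholds of the three-tier resilience classification
#'
#' @param drop_small NDVI drop below which a pixel counts as lightly
#'   impacted (default 0.1).
#' @param drop_large NDVI drop above which a pixel counts as severely
#'   impacted (default 0.2).
#' @param t_fast Recovery time (yr) at or below which recovery counts as
#'   rapid (default 5).
#' @param t_slow Recovery time (yr) above which recovery counts as failed
#'   (default 15).
#' @return A list of class `resilience_thresholds`.
#' @export
resilience_thresholds <- function(drop_small = 0.1, drop_large = 0.2,
                                  t_fast = 5, t_slow = 15) {
  stopifnot(0 < drop_small, drop_small < drop_large, 0 < t_fast,
            t_fast < t_slow)
  structure(list(drop_small = drop_small, drop_large = drop_large,
                 t_fast = t_fast, t_slow = t_slow),
            class = "resilience_thresholds")
}

#' Median composite of a scene stack over a date window
#'
#' Per-pixel, per-band median over all valid (cloud-free) observations in
#' the window, the standard cloud-robust reference mosaic. NDVI is computed
#' per scene and composited as its own band. Pixels with no valid
#' observation in the window are `NA`.
#'
#' @param stack A [scene_stack()].
#' @param window Length-2 date pair.
#' @return A tibble with `row`, `col`, `red`, `nir`, `ndvi` and `n_obs`
#'   (valid observations used).
#' @export
median_composite <- function(stack, window) {
  stopifnot(inherits(stack, "scene_stack"))
  cols <- window_cols(stack, window)
  if (!length(cols)) {
    warning("no scenes fall in the compositing window; all-NA composite")
    return(dplyr::mutate(stack$pixel_index, red = NA_real_, nir = NA_real_,
                         ndvi = NA_real_, n_obs = 0L))
  }
  med_band <- function(m) {
    mm <- m[, cols, drop = FALSE]
    mm[!stack$valid[, cols, drop = FALSE]] <- NA
    apply(mm, 1, median, na.rm = TRUE)
  }
  red <- med_band(stack$red)
  nir <- med_band(stack$nir)
  nd <- med_band(ndvi_matrix(stack))
  n_obs <- rowSums(stack$valid[, cols, drop = FALSE])
  out <- dplyr::mutate(stack$pixel_index,
                       red = red, nir = nir, ndvi = nd,
                       n_obs = as.integer(n_obs))
  out$red[out$n_obs == 0L] <- NA
  out$nir[out$n_obs == 0L] <- NA
  out$ndvi[out$n_obs == 0L] <- NA
  out
}

#' Mean NDVI anomaly over a window
#'
#' For each pixel, the mean over all valid in-window observations of
#' `NDVI_t - ndvi_ref`: the sum of per-scene anomalies normalized by the
#' number of valid observations. Pixels with no valid observation are `NA`.
#'
#' @param stack A [scene_stack()].
#' @param ndvi_ref Per-pixel reference NDVI (vector aligned with the stack's
#'   pixel index, typically the pre-storm composite's `ndvi`).
#' @param window Length-2 date pair.
#' @return A tibble with `row`, `col`, `mean_anomaly`, `n_obs`.
#' @export
mean_anomaly <- function(stack, ndvi_ref, window) {
  stopifnot(inherits(stack, "scene_stack"),
            length(ndvi_ref) == nrow(stack$red))
  cols <- window_cols(stack, window)
  v <- ndvi_matrix(stack)[, cols, drop = FALSE]
  val <- stack$valid[, cols, drop = FALSE]
  anom <- (v - ndvi_ref) * val
  anom[!val] <- 0
  n_obs <- rowSums(val)
  out <- rowSums(anom) / n_obs
  out[n_obs == 0] <- NA
  dplyr::mutate(stack$pixel_index, mean_anomaly = out,
                n_obs = as.integer(n_obs))
}

#' Per-pixel NDVI trend over a window
#'
#' Ordinary least-squares slope of NDVI against time (in years) over the
#' valid observations in the window, plus the fitted NDVI at the window's
#' end — the noise-robust anchor used for recovery-time estimation. Pixels
#' with fewer than two valid observations (or no time spread) are `NA`.
#'
#' @param stack A [scene_stack()].
#' @param window Length-2 date pair (typically the slope window of
#'   [composite_config()]).
#' @return A tibble with `row`, `col`, `slope` (NDVI/yr), `ndvi_fit_end`
#'   (fitted NDVI at the window end) and `n_obs`.
#' @export
ndvi_slope <- function(stack, window) {
  stopifnot(inherits(stack, "scene_stack"))
  cols <- window_cols(stack, window)
  v <- ndvi_matrix(stack)[, cols, drop = FALSE]
  val <- stack$valid[, cols, drop = FALSE]
  t_yr <- as_years(stack$dates[cols])
  t_end <- as_years(as.Date(window[[2]]))

  w <- val * 1
  y <- v
  y[!val] <- 0
  tm <- matrix(t_yr, nrow(v), ncol(v), byrow = TRUE)
  n <- rowSums(w)
  st <- rowSums(w * tm)
  sy <- rowSums(y)
  stt <- rowSums(w * tm^2)
  sty <- rowSums(tm * y)
  denom <- n * stt - st^2
  slope <- (n * sty - st * sy) / denom
  intercept <- (sy - slope * st) / n
  bad <- n < 2 | abs(denom) < 1e-12
  slope[bad] <- NA
  intercept[bad] <- NA
  dplyr::mutate(stack$pixel_index,
                slope = slope,
                ndvi_fit_end = intercept + slope * t_end,
                n_obs = as.integer(n))
}

#' Time to full NDVI recovery
#'
#' Linear extrapolation of the fitted post-storm NDVI trend to the pre-storm
#' reference level: `deficit / slope` years beyond the slope window's end,
#' where `deficit = ndvi_ref - ndvi_fit_end`. Pixels already at or above the
#' reference (`deficit <= 0`) get 0 years; pixels with a non-positive slope
#' are not assigned a recovery time (`NA`), since a flat or browning trend
#' never reaches the reference.
#'
#' @param deficit `ndvi_ref - ndvi_fit_end` (NDVI units); vectorized.
#' @param slope NDVI trend, NDVI/yr; vectorized.
#' @return Recovery time in years (`NA` where unassigned).
#' @examples
#' recovery_time(0.15, 0.03)   # 5 years
#' recovery_time(0.15, -0.01)  # unassigned
#' recovery_time(-0.02, 0.03)  # already recovered
#' @export
recovery_time <- function(deficit, slope) {
  out <- ifelse(deficit <= 0, 0, deficit / slope)
  out[is.na(slope) | slope <= 0] <- NA
  out
}

#' Three-tier resilience classification
#'
#' Classifies each pixel as `high`, `low` or `intermediate` from its
#' post-storm NDVI drop (`drop = -mean_anomaly`, positive-drop scale),
#' recovery diagnostics and wind exposure:
#'
#' * **high** — observed to recover within the first post-storm year
#'   (`recovered`), predicted to recover within `t_fast` years regardless of
#'   the drop, or a small drop (< `drop_small`) despite storm-force winds
#'   (`wind_ok`);
#' * **low** (dieback) — a large drop (> `drop_large`) combined with failed
#'   recovery: predicted recovery beyond `t_slow` years, a non-positive
#'   slope, or no assigned recovery time;
#' * **intermediate** — everything else: predicted recovery between `t_fast`
#'   and `t_slow` years, or stalled/slow recovery with a moderate drop.
#'
#' Rules are applied in the precedence high, then low, then intermediate, so
#' the classification is total and mutually exclusive; pixels with missing
#' inputs return `NA`.
#'
#' @param drop Post-storm NDVI drop, positive scale (`-mean_anomaly`).
#' @param slope Post-storm NDVI trend, NDVI/yr.
#' @param recov_time Predicted recovery time, yr (`NA` = unassigned).
#' @param recovered Logical: observed back at the pre-storm reference by the
#'   end of the first post-storm year.
#' @param wind_ok Logical: exposed to at least tropical-storm-force winds
#'   (the lowest wind class qualifies every study pixel by default).
#' @param thresholds A [resilience_thresholds()].
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @examples
#' resilience_class(drop = 0.25, slope = -0.005, recov_time = NA,
#'                  recovered = FALSE)                      # low
#' resilience_class(drop = 0.3, slope = 0.1, recov_time = 3,
#'                  recovered = FALSE)                      # high
#' resilience_class(drop = 0.15, slope = 0.02, recov_time = 9,
#'                  recovered = FALSE)                      # intermediate
#' @export
resilience_class <- function(drop, slope, recov_time, recovered,
                             wind_ok = TRUE,
                             thresholds = resilience_thresholds()) {
  stopifnot(inherits(thresholds, "resilience_thresholds"))
  n <- max(length(drop), length(slope), length(recov_time),
           length(recovered), length(wind_ok))
  drop <- rep_len(drop, n)
  slope <- rep_len(slope, n)
  recov_time <- rep_len(recov_time, n)
  recovered <- rep_len(recovered, n)
  wind_ok <- rep_len(wind_ok, n)

  has_t <- !is.na(recov_time)
  high <- (!is.na(recovered) & recovered) |
    (has_t & recov_time <= thresholds$t_fast) |
    (!is.na(drop) & drop < thresholds$drop_small & wind_ok)
  failed <- (has_t & recov_time > thresholds$t_slow) |
    (!is.na(slope) & slope <= 0) | (!has_t)
  low <- !high & !is.na(drop) & drop > thresholds$drop_large & failed

  out <- rep(NA_character_, n)
  out[!is.na(drop) & !high & !low] <- "intermediate"
  out[low] <- "low"
  out[high] <- "high"
  out[is.na(drop)] <- NA
  factor(out, levels = resilience_levels())
}

#' Classify resilience for a pixel table
#'
#' Data-frame interface to [resilience_class()]: expects columns
#' `mean_anomaly`, `slope`, `recovery_time`, `recovered` and (optionally)
#' `wind_ok`, and appends `drop` and `resilience`.
#'
#' @param data Pixel tibble.
#' @param thresholds A [resilience_thresholds()].
#' @return `data` with `drop` and `resilience` columns.
#' @export
classify_resilience <- function(data, thresholds = resilience_thresholds()) {
  need <- c("mean_anomaly", "slope", "recovery_time", "recovered")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "))
  }
  wind_ok <- if ("wind_ok" %in% names(data)) data$wind_ok else TRUE
  dplyr::mutate(
    data,
    drop = -.data$mean_anomaly,
    resilience = resilience_class(.data$drop, .data$slope,
                                  .data$recovery_time, .data$recovered,
                                  wind_ok, thresholds)
  )
}

#' Full recovery and resilience assessment of a scene stack
#'
#' Runs the headline inference chain for every pixel: pre-storm reference
#' NDVI from the median composite, mean NDVI anomaly over the post-storm
#' window, NDVI trend over the slope window, recovery time, the
#' observed-recovery flag (mean anomaly over the final 90 days of the slope
#' window at or above zero), and the three-tier classification.
#'
#' @param stack A [scene_stack()].
#' @param composites A [composite_config()].
#' @param thresholds A [resilience_thresholds()].
#' @param wind_ok Logical vector (or scalar) per pixel: qualifies for the
#'   small-drop high-resilience rule. Defaults to `TRUE` everywhere.
#' @param mask Optional logical vector: pixels outside the mask get `NA`
#'   results.
#' @return A tibble with one row per pixel: `row`, `col`, `ndvi_ref`,
#'   `mean_anomaly`, `drop`, `slope`, `ndvi_fit_end`, `deficit`,
#'   `recovery_time`, `recovered`, `resilience`.
#' @export
assess_resilience <- function(stack, composites = composite_config(),
                              thresholds = resilience_thresholds(),
                              wind_ok = TRUE, mask = NULL) {
  stopifnot(inherits(stack, "scene_stack"),
            inherits(composites, "composite_config"))
  pre <- median_composite(stack, composites$pre_window)
  anom <- mean_anomaly(stack, pre$ndvi, composites$anomaly_window)
  trend <- ndvi_slope(stack, composites$slope_window)
  end_win <- c(as.Date(composites$slope_window[[2]]) - 90,
               composites$slope_window[[2]])
  tail_anom <- mean_anomaly(stack, pre$ndvi, end_win)

  out <- tibble::tibble(
    row = stack$pixel_index$row,
    col = stack$pixel_index$col,
    ndvi_ref = pre$ndvi,
    mean_anomaly = anom$mean_anomaly,
    slope = trend$slope,
    ndvi_fit_end = trend$ndvi_fit_end,
    recovered = !is.na(tail_anom$mean_anomaly) & tail_anom$mean_anomaly >= 0,
    wind_ok = rep_len(wind_ok, nrow(stack$pixel_index))
  )
  out <- dplyr::mutate(
    out,
    deficit = .data$ndvi_ref - .data$ndvi_fit_end,
    recovery_time = recovery_time(.data$deficit, .data$slope)
  )
  out <- classify_resilience(out, thresholds)
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(out))
    out$resilience[!mask] <- NA
  }
  out
}
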
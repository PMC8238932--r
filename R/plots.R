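#' Map a per-pixel variable or class
#'
#' Renders a pixel tibble column as a raster map (rows increase downward,
#' matching the row-major, origin-top-left grid convention).
#'
#' @param data Pixel tibble with `row` and `col`.
#' @param fill Column name to map.
#' @return A ggplot object.
#' @export
plot_pixel_map <- function(data, fill) {
  stopifnot(all(c("row", "col", fill) %in% names(data)))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data[[fill]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = fill) +
    ggplot2::theme_minimal()
}

#' Map of resilience classes
#'
#' @param data Pixel tibble with `row`, `col` and a `resilience` column.
#' @return A ggplot object with the conventional dieback-to-recovery
#'   palette (low = brown, intermediate = gold, high = green).
#' @export
plot_resilience_map <- function(data) {
  plot_pixel_map(data, "resilience") +
    ggplot2::scale_fill_manual(
      values = c(low = "#8c510a", intermediate = "#f6e8c3",
                 high = "#01665e"),
      na.value = "grey90", drop = FALSE
    )
}

#' @method autoplot damage_summary
#' @export
autoplot.damage_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$height_class, y = .data$mean_loss_m,
                               fill = .data$area_ha)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_loss_m - .data$se_m,
                   ymax = .data$mean_loss_m + .data$se_m),
      width = 0.25
    ) +
    ggplot2::facet_wrap(~wind_class) +
    ggplot2::labs(x = "pre-storm height class",
                  y = "mean canopy height loss (m)",
                  fill = "area (ha)") +
    ggplot2::theme_minimal()
}

#' @method autoplot ks_report
#' @export
autoplot.ks_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pair, y = .data$d_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$d_q1,
                                          ymax = .data$d_q3)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$d_crit),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "KS statistic (mean, Q1-Q3)") +
    ggplot2::theme_minimal()
}

#' @method autoplot class_distribution
#' @export
autoplot.class_distribution <- function(object, ...) {
  ggplot2::ggplot(object$cdf,
                  ggplot2::aes(x = .data$value, y = .data$cum_fraction,
                               colour = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = object$covariate, y = "cumulative fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
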
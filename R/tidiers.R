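#' Tidy a bias correction fit
#'
#' @param x A [fit_bias_correction()] object.
#' @param conf.level Confidence level for the interval columns.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy bias_correction
#' @export
tidy.bias_correction <- function(x, conf.level = 0.95, ...) {
  ci <- confint(x$fit, level = conf.level)
  se <- sqrt(diag(vcov(x$fit)))
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(se),
    conf.low = ci[, 1],
    conf.high = ci[, 2]
  )
}

#' @rdname tidy.bias_correction
#' @method glance bias_correction
#' @export
glance.bias_correction <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared, rmse = x$rmse, n_samples = x$n_samples,
    seed = x$seed
  )
}

#' Tidy an ANOVA/Tukey damage test
#'
#' @param x An [anova_tukey()] object.
#' @param ... Unused.
#' @return `tidy()`: the Tukey pairwise table (`pair`, `diff`, `lwr`,
#'   `upr`, `p_adj`, `significant`). `glance()`: one row with the F test.
#' @method tidy damage_anova
#' @export
tidy.damage_anova <- function(x, ...) x$pairs

#' @rdname tidy.damage_anova
#' @method glance damage_anova
#' @export
glance.damage_anova <- function(x, ...) {
  tibble::tibble(
    f_statistic = x$f_statistic, p_value = x$p_value,
    df_between = unname(x$df[1]), df_within = unname(x$df[2]),
    alpha = x$alpha
  )
}

#' Tidy an error matrix
#'
#' @param x An [error_matrix()] object.
#' @param ... Unused.
#' @return `tidy()`: long confusion counts (`reference`, `predicted`, `n`).
#'   `glance()`: one row with `overall_accuracy` and `n`.
#' @method tidy error_matrix
#' @export
tidy.error_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$counts, responseName = "n"))
}

#' @rdname tidy.error_matrix
#' @method glance error_matrix
#' @export
glance.error_matrix <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$overall_accuracy, n = x$n)
}
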
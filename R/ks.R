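#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum distance between the empirical cumulative distribution
#' functions of two samples, `D = sup |ECDF_x - ECDF_y|`. Ties within and
#' across samples are handled by evaluating the ECDF difference at the last
#' occurrence of each distinct value.
#'
#' @param x,y Non-empty numeric samples.
#' @return `D` in `[0, 1]`.
#' @examples
#' ks_statistic(c(1, 2, 3), c(1, 2, 4)) # 1/3
#' @export
ks_statistic <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x)
  m <- length(y)
  z <- c(x, y)
  o <- order(z)
  steps <- c(rep(1 / n, n), rep(-1 / m, m))[o]
  cw <- cumsum(steps)
  zs <- z[o]
  last <- c(zs[-1] != zs[-length(zs)], TRUE)
  max(abs(cw[last]))
}

# coefficients of the asymptotic two-sample critical value, c(alpha)
ks_alpha_coefficients <- c(
  "0.1" = 1.22, "0.05" = 1.358, "0.025" = 1.48,
  "0.01" = 1.628, "0.005" = 1.731, "0.001" = 1.949
)

#' Critical value of the two-sample KS statistic
#'
#' Asymptotic critical value `c(alpha) * sqrt((n + m) / (n * m))` with the
#' standard tabulated coefficients (`c(0.05) = 1.358`). Alphas without a
#' tabulated coefficient are an error.
#'
#' @param n,m Sample sizes (>= 1).
#' @param alpha Significance level; one of 0.1, 0.05, 0.025, 0.01, 0.005,
#'   0.001.
#' @return The critical value `D_crit`.
#' @examples
#' ks_critical(500, 500) # ~0.0859
#' @export
ks_critical <- function(n, m, alpha = 0.05) {
  stopifnot(n >= 1, m >= 1)
  key <- format(alpha, trim = TRUE)
  if (!key %in% names(ks_alpha_coefficients)) {
    stop("no tabulated coefficient for alpha = ", alpha)
  }
  unname(ks_alpha_coefficients[key]) * sqrt((n + m) / (n * m))
}

#' Configuration of the iterated KS comparison
#'
#' Two-stage resampling scheme: a seeded pool of `n_pool_per_class` pixels
#' is drawn once per class, then each iteration draws `n_per_iteration`
#' points per class from its pool (both without replacement) and computes
#' the KS statistic for every class pair and variable.
#'
#' @param n_pool_per_class Pool size per class (default 10000).
#' @param n_per_iteration Points per class per iteration (default 500).
#' @param iterations Number of iterations (default 5000).
#' @param alpha Significance level for the critical value.
#' @param seed Integer seed.
#' @return A list of class `ks_config`.
#' @export
ks_config <- function(n_pool_per_class = 10000, n_per_iteration = 500,
                      iterations = 5000, alpha = 0.05, seed = 1) {
  stopifnot(iterations >= 1, n_per_iteration >= 1,
            n_per_iteration <= n_pool_per_class)
  structure(list(n_pool_per_class = as.integer(n_pool_per_class),
                 n_per_iteration = as.integer(n_per_iteration),
                 iterations = as.integer(iterations),
                 alpha = alpha, seed = as.integer(seed)),
            class = "ks_config")
}

#' Iterated KS comparison of variables across classes
#'
#' For every pair of classes and every variable, repeatedly draws
#' `n_per_iteration` pixels per class (from per-class pools sampled once up
#' front) and computes the two-sample KS statistic; one point sample per
#' class per iteration is shared across all variables. Reports the mean and
#' first/third quartiles of `D` over iterations, the asymptotic critical
#' value, and significance (`d_mean > d_crit`) — a resampling-robust summary
#' of how strongly each environmental variable separates the classes.
#'
#' @param data Pixel tibble holding the class column and the variables.
#' @param class_col Column name of the class labels; at least two classes
#'   with valid pixels are required.
#' @param variables Character vector of variable column names.
#' @param config A [ks_config()]. Classes with fewer than
#'   `n_pool_per_class` valid pixels contribute all their pixels (with a
#'   warning).
#' @return A tibble of class `ks_report`: `variable`, `pair`, `d_mean`,
#'   `d_q1`, `d_q3`, `d_crit`, `significant`.
#' @export
iterated_ks <- function(data, class_col, variables, config = ks_config()) {
  stopifnot(inherits(config, "ks_config"),
            class_col %in% names(data), all(variables %in% names(data)))
  cls <- factor(data[[class_col]])
  ok <- !is.na(cls) & complete.cases(as.data.frame(data[, variables]))
  classes <- levels(droplevels(cls[ok]))
  if (length(classes) < 2L) stop("need at least 2 classes with valid pixels")

  # stage 1: one pool per class
  pools <- withr::with_seed(stage_seed(config$seed, "pool"), {
    lapply(setNames(classes, classes), function(cl) {
      pool <- which(ok & cls == cl)
      if (length(pool) < config$n_pool_per_class) {
        warning("class '", cl, "' has only ", length(pool),
                " valid pixels; pooling all")
        pool
      } else {
        sample(pool, config$n_pool_per_class)
      }
    })
  })
  n_it <- config$n_per_iteration
  vars <- lapply(setNames(variables, variables),
                 function(v) as.numeric(data[[v]]))
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  d_crit <- ks_critical(n_it, n_it, config$alpha)

  # stage 2: iterate; one pixel draw per class per iteration, shared by all
  # variables
  d <- array(NA_real_,
             dim = c(config$iterations, length(pairs), length(variables)))
  withr::with_seed(stage_seed(config$seed, "ks"), {
    for (it in seq_len(config$iterations)) {
      draw <- lapply(pools, function(p) {
        if (length(p) <= n_it) p else p[sample.int(length(p), n_it)]
      })
      for (pi in seq_along(pairs)) {
        a <- draw[[pairs[[pi]][1]]]
        b <- draw[[pairs[[pi]][2]]]
        for (vi in seq_along(variables)) {
          v <- vars[[vi]]
          d[it, pi, vi] <- ks_statistic(v[a], v[b])
        }
      }
    }
  })

  out <- tidyr::expand_grid(
    variable = variables,
    pair = vapply(pairs, paste, character(1), collapse = "-")
  )
  stat <- purrr::pmap(out, function(variable, pair) {
    pi <- match(pair, vapply(pairs, paste, character(1), collapse = "-"))
    vi <- match(variable, variables)
    di <- d[, pi, vi]
    tibble::tibble(d_mean = mean(di),
                   d_q1 = unname(quantile(di, 0.25)),
                   d_q3 = unname(quantile(di, 0.75)),
                   rejection_rate = mean(di > d_crit))
  })
  out <- dplyr::bind_cols(out, dplyr::bind_rows(stat))
  out <- dplyr::mutate(out, d_crit = d_crit,
                       significant = .data$d_mean > d_crit)
  class(out) <- c("ks_report", class(out))
  attr(out, "config") <- config
  out
}

#' Percent canopy height loss
#'
#' `100 * (chm_pre - chm_post) / chm_pre`, with pixels shorter than
#' `min_height` before the storm excluded (`NA`) to guard the division.
#'
#' @param chm_pre,chm_post Canopy heights, m.
#' @param min_height Minimum pre-storm height to evaluate, m.
#' @return Percent loss, same length.
#' @export
percent_height_loss <- function(chm_pre, chm_post, min_height = 0.5) {
  out <- 100 * (chm_pre - chm_post) / chm_pre
  out[is.na(chm_pre) | chm_pre < min_height] <- NA
  out
}
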
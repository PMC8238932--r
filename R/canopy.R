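#' Calibrate stereo surface heights against lidar canopy heights
#'
#' Fits the linear bias-correction equation mapping stereo-DSM values to
#' lidar canopy heights, `chm = intercept + slope * dsm`, from a seeded
#' random sample of pixels inside the forest mask (sampling without
#' replacement). The linear form is the minimal defensible model for a
#' single DSM-lidar scatter; the fitted object carries the OLS fit, so any
#' richer form can be swapped in upstream.
#'
#' @param data Pixel tibble.
#' @param dsm,chm Column names (strings) of the stereo DSM and lidar CHM.
#' @param mask Optional logical vector or column name restricting the
#'   sampling frame (e.g. the mangrove mask).
#' @param n Number of calibration points to sample (default 1000). If fewer
#'   valid pixels exist, all are used with a warning.
#' @param seed Integer seed for the sample draw.
#' @return An object of class `bias_correction`: coefficients, `rmse`,
#'   `n_samples`, the underlying `lm` fit. Supports [tidy()], [glance()],
#'   [predict()].
#' @examples
#' px <- tibble::tibble(chm = runif(2000, 0, 20))
#' px$dsm <- 2 + 0.9 * px$chm + rnorm(2000, sd = 0.1)
#' fit_bias_correction(px, "dsm", "chm", seed = 1)
#' @export
fit_bias_correction <- function(data, dsm = "dsm_pre", chm = "chm_pre",
                                mask = NULL, n = 1000, seed = 1) {
  stopifnot(is.data.frame(data), dsm %in% names(data), chm %in% names(data))
  keep <- !is.na(data[[dsm]]) & !is.na(data[[chm]])
  if (!is.null(mask)) {
    m <- if (is.character(mask) && length(mask) == 1L) data[[mask]] else mask
    keep <- keep & !is.na(m) & as.logical(m)
  }
  idx <- which(keep)
  if (length(idx) < 2L) stop("need at least 2 valid calibration pixels")
  if (length(idx) < n) {
    warning("only ", length(idx), " valid pixels available; using all")
    n <- length(idx)
  }
  sampled <- withr::with_seed(seed, sample(idx, n))
  x <- data[[dsm]][sampled]
  y <- data[[chm]][sampled]
  if (length(unique(x)) < 2L) stop("degenerate regressor: DSM is constant")
  fit <- lm(y ~ x)
  res <- unname(fit$residuals)
  structure(
    list(
      intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
      n_samples = n, rmse = sqrt(mean(res^2)), seed = seed, fit = fit
    ),
    class = "bias_correction"
  )
}

#' @export
print.bias_correction <- function(x, ...) {
  cat("<bias_correction> chm = ", signif(x$intercept, 5), " + ",
      signif(x$slope, 5), " * dsm  (n = ", x$n_samples,
      ", rmse = ", signif(x$rmse, 4), " m)\n", sep = "")
  invisible(x)
}

#' Test whether a bias correction covers reference parameters
#'
#' Checks whether `(intercept, slope)` lies inside the fit's joint
#' `level` confidence ellipse (the standard F-based confidence region for
#' an OLS coefficient pair).
#'
#' @param bc A [fit_bias_correction()] object.
#' @param intercept,slope Reference parameter values.
#' @param level Confidence level (default 0.95).
#' @return Logical.
#' @export
bias_correction_covers <- function(bc, intercept, slope, level = 0.95) {
  stopifnot(inherits(bc, "bias_correction"))
  beta <- coef(bc$fit)
  diff <- beta - c(intercept, slope)
  v <- vcov(bc$fit)
  stat <- drop(t(diff) %*% solve(v, diff)) / 2
  stat <= qf(level, 2, bc$fit$df.residual)
}

#' Apply a bias correction to a stereo DSM
#'
#' Per-pixel `intercept + slope * dsm`, with negative corrected heights
#' clipped to zero (canopy height cannot be negative). `NA` propagates.
#'
#' @param dsm DSM values (vector or matrix).
#' @param bc A [fit_bias_correction()] object (or anything with `intercept`
#'   and `slope` elements).
#' @return Corrected canopy heights, same shape.
#' @export
apply_bias_correction <- function(dsm, bc) {
  pmax(bc$intercept + bc$slope * dsm, 0)
}

#' Canopy volume
#'
#' Total canopy volume: the sum of per-pixel canopy height times cell area
#' over the (optionally masked) valid pixels.
#'
#' @param chm Canopy heights, m (vector).
#' @param mask Optional logical vector of pixels to include.
#' @param cell_size Cell edge length, m.
#' @return Volume in cubic metres.
#' @examples
#' canopy_volume(rep(10, 100), cell_size = 1) # 1000 m^3
#' @export
canopy_volume <- function(chm, mask = NULL, cell_size = 30) {
  if (!is.null(mask)) chm <- chm[as.logical(mask) & !is.na(mask)]
  sum(chm, na.rm = TRUE) * cell_size^2
}

#' Canopy height loss summarized by height and wind class
#'
#' Computes per-pixel height loss `chm_pre - chm_post`, stratifies pixels by
#' pre-storm height class and maximum-wind class, and reports the mean loss,
#' its standard error (`sd / sqrt(n)`, pixel-population SE) and the area of
#' every populated class cell. Pixels falling outside either bin range, or
#' with missing inputs, are excluded.
#'
#' @param data Pixel tibble with `chm_pre`, `chm_post` and `max_wind`
#'   columns (names configurable).
#' @param height_bins,wind_bins [class_bins()] for the two stratifications.
#' @param chm_pre,chm_post,wind Column names.
#' @param mask Optional logical vector or column name (e.g. mangrove mask).
#' @param cell_size Cell edge length, m.
#' @return A tibble of class `damage_summary`: `height_class`, `wind_class`,
#'   `mean_loss_m`, `se_m`, `n_pixels`, `area_ha`; empty cells are omitted.
#' @export
damage_summary <- function(data, height_bins = height_class_bins(),
                           wind_bins = wind_class_bins(),
                           chm_pre = "chm_pre", chm_post = "chm_post",
                           wind = "max_wind", mask = NULL, cell_size = 30) {
  stopifnot(all(c(chm_pre, chm_post, wind) %in% names(data)))
  keep <- rep(TRUE, nrow(data))
  if (!is.null(mask)) {
    m <- if (is.character(mask) && length(mask) == 1L) data[[mask]] else mask
    keep <- !is.na(m) & as.logical(m)
  }
  df <- tibble::tibble(
    loss = data[[chm_pre]][keep] - data[[chm_post]][keep],
    height_class = bin_values(data[[chm_pre]][keep], height_bins),
    wind_class = bin_values(data[[wind]][keep], wind_bins)
  )
  df <- dplyr::filter(df, !is.na(.data$loss), !is.na(.data$height_class),
                      !is.na(.data$wind_class))
  out <- df |>
    dplyr::group_by(.data$height_class, .data$wind_class) |>
    dplyr::summarise(
      mean_loss_m = mean(.data$loss),
      se_m = if (dplyr::n() > 1) sd(.data$loss) / sqrt(dplyr::n()) else 0,
      n_pixels = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(area_ha = .data$n_pixels * cell_size^2 / 1e4)
  class(out) <- c("damage_summary", class(out))
  out
}

#' One-way ANOVA with post-hoc Tukey HSD and compact letters
#'
#' Tests for differences in a response (canopy height loss) across class
#' groups with a one-way ANOVA, follows up with Tukey's honest significant
#' difference test on all pairs, and assigns compact letter display (CLD)
#' groupings: classes sharing a letter are not significantly different at
#' `alpha`.
#'
#' @param data Tibble of per-pixel (or per-sample) values.
#' @param value,group Column names of the response and the grouping factor.
#' @param alpha Significance level for the Tukey pairs and letters.
#' @return An object of class `damage_anova` with elements `f_statistic`,
#'   `p_value`, `df`, `pairs` (tibble of Tukey-adjusted pairwise results),
#'   `letters` (tibble of per-group means and CLD letters) and `alpha`.
#'   Supports [tidy()] and [glance()].
#' @examples
#' df <- tibble::tibble(g = rep(c("a", "b"), each = 30),
#'                      y = rnorm(60) + rep(c(0, 2), each = 30))
#' anova_tukey(df, "y", "g")
#' @export
anova_tukey <- function(data, value, group, alpha = 0.05) {
  stopifnot(value %in% names(data), group %in% names(data))
  df <- tibble::tibble(
    y = as.numeric(data[[value]]),
    g = factor(data[[group]])
  )
  df <- df[complete.cases(df), ]
  df$g <- droplevels(df$g)
  counts <- table(df$g)
  if (length(counts) < 2L) stop("need at least 2 groups")
  if (any(counts < 2L)) stop("every group needs at least 2 samples")
  fit <- aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  f_stat <- an[["F value"]][1]
  p_val <- an[["Pr(>F)"]][1]
  if (sd(df$y) < 1e-12 * (1 + abs(mean(df$y)))) {
    # zero variance everywhere: the F ratio is 0/0
    f_stat <- NaN
    p_val <- NaN
  }

  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  combos <- utils::combn(levels(df$g), 2) # row order used by TukeyHSD
  pairs <- tibble::tibble(
    pair = rownames(tk),
    group_a = combos[1, ],
    group_b = combos[2, ],
    diff = unname(tk[, "diff"]),
    lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]),
    p_adj = unname(tk[, "p adj"]),
    # degenerate fits (zero residual variance) give NaN p-values: not
    # evidence of a difference
    significant = !is.na(p_adj) & p_adj < alpha & is.finite(f_stat)
  )
  means <- df |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(mean = mean(.data$y), n = dplyr::n(), .groups = "drop")
  letters_tb <- dplyr::mutate(
    means,
    letters = cld_letters(levels(df$g), pairs$group_a, pairs$group_b,
                          pairs$significant)
  )
  structure(
    list(f_statistic = f_stat, p_value = p_val,
         df = c(between = an$Df[1], within = an$Df[2]),
         pairs = pairs,
         letters = dplyr::rename(letters_tb, group = "g"),
         alpha = alpha),
    class = "damage_anova"
  )
}

#' @export
print.damage_anova <- function(x, ...) {
  cat("<damage_anova> F(", x$df[1], ", ", x$df[2], ") = ",
      signif(x$f_statistic, 5), ", p = ", format.pval(x$p_value, digits = 3),
      "\n", sep = "")
  print(x$letters)
  invisible(x)
}

# Compact letter display by the standard insert-and-absorb greedy algorithm:
# walk the groups in order, start a new letter whenever a group conflicts
# with every existing letter set, then absorb groups into any set they do
# not conflict with.
cld_letters <- function(groups, pair_a, pair_b, pair_significant) {
  sig <- matrix(FALSE, length(groups), length(groups),
                dimnames = list(groups, groups))
  for (k in seq_along(pair_a)) {
    sig[pair_a[k], pair_b[k]] <- sig[pair_b[k], pair_a[k]] <- pair_significant[k]
  }
  sets <- list()
  for (g in groups) {
    placed <- FALSE
    for (i in seq_along(sets)) {
      if (!any(sig[g, sets[[i]]])) {
        sets[[i]] <- c(sets[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) {
      # seed a new letter set with g, then absorb earlier compatible groups
      s <- g
      for (h in groups[seq_len(match(g, groups) - 1L)]) {
        if (!any(sig[h, s])) s <- c(s, h)
      }
      sets[[length(sets) + 1L]] <- s
    }
  }
  # drop sets wholly contained in another (can arise from absorption order)
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && keep[j] && all(sets[[i]] %in% sets[[j]])) keep[i] <- FALSE
    }
  }
  sets <- sets[keep]
  vapply(groups, function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
           collapse = "")
  }, character(1))
}
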
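#' Distribution of a covariate within each resilience class
#'
#' Per-class summary of an environmental covariate (ground elevation, surge
#' depth, canopy height...): median, quartiles, area, and the empirical
#' cumulative distribution evaluated on a regular value grid of width
#' `bin_width`.
#'
#' @param data Pixel tibble.
#' @param class_col Column name of the class labels (e.g. `"resilience"`).
#' @param covariate Column name of the covariate.
#' @param bin_width Spacing of the CDF evaluation grid, in covariate units
#'   (e.g. 0.01 m for elevation, 0.1 m for surge depth). Purely
#'   presentational.
#' @param cell_size Cell edge length, m.
#' @return A list of class `class_distribution` with `summary` (tibble:
#'   `class`, `median`, `q1`, `q3`, `n_pixels`, `area_ha`) and `cdf`
#'   (tibble: `class`, `value`, `cum_fraction`, monotone from 0 to 1).
#' @export
class_distribution <- function(data, class_col, covariate, bin_width = 0.1,
                               cell_size = 30) {
  stopifnot(class_col %in% names(data), covariate %in% names(data),
            bin_width > 0)
  df <- tibble::tibble(
    class = factor(data[[class_col]]),
    value = as.numeric(data[[covariate]])
  )
  df <- dplyr::filter(df, !is.na(.data$class), !is.na(.data$value))
  if (!nrow(df)) stop("no valid pixels")
  empty <- setdiff(levels(df$class), as.character(unique(df$class)))
  if (length(empty)) {
    warning("empty class(es) omitted: ", paste(empty, collapse = ", "))
  }
  df$class <- droplevels(df$class)
  summ <- df |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      median = median(.data$value),
      q1 = unname(quantile(.data$value, 0.25)),
      q3 = unname(quantile(.data$value, 0.75)),
      n_pixels = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(area_ha = .data$n_pixels * cell_size^2 / 1e4)
  # one bin below the minimum so every curve starts at 0
  grid <- seq(floor(min(df$value) / bin_width) * bin_width - bin_width,
              ceiling(max(df$value) / bin_width) * bin_width,
              by = bin_width)
  cdf <- df |>
    dplyr::group_by(.data$class) |>
    dplyr::reframe(
      cum_fraction = stats::ecdf(.data$value)(grid),
      value = grid
    ) |>
    dplyr::select("class", "value", "cum_fraction")
  structure(list(summary = summ, cdf = tibble::as_tibble(cdf),
                 covariate = covariate, bin_width = bin_width),
            class = "class_distribution")
}

#' @export
print.class_distribution <- function(x, ...) {
  cat("<class_distribution> of ", x$covariate, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Fraction of a class above a covariate threshold
#'
#' The fraction of a class's pixels whose covariate exceeds `threshold`
#' (strictly), e.g. the share of dieback pixels flooded deeper than 1.4 m.
#'
#' @inheritParams class_distribution
#' @param class_id Class to evaluate.
#' @param threshold Covariate threshold.
#' @return A fraction in `[0, 1]`, or `NA` if the class is empty.
#' @export
exceedance_fraction <- function(data, class_col, covariate, class_id,
                                threshold) {
  stopifnot(class_col %in% names(data), covariate %in% names(data))
  v <- data[[covariate]][!is.na(data[[class_col]]) &
                           as.character(data[[class_col]]) == class_id]
  v <- v[!is.na(v)]
  if (!length(v)) {
    warning("class '", class_id, "' empty; exceedance undefined")
    return(NA_real_)
  }
  mean(v > threshold)
}

#' Resilience area cross-tabulated by dominant species
#'
#' Hectares of each (species, resilience) combination plus the share of each
#' species' area in each resilience class (`row_share`) and of each
#' resilience class across species (`col_share`). Pixels with an unknown or
#' missing species label are bucketed as `"other"` with a warning.
#'
#' @param data Pixel tibble with species and resilience columns.
#' @param species_col,class_col Column names.
#' @param cell_size Cell edge length, m.
#' @return A tibble: `species`, `resilience`, `n_pixels`, `area_ha`,
#'   `row_share`, `col_share`.
#' @export
area_by_species <- function(data, species_col = "species",
                            class_col = "resilience", cell_size = 30) {
  stopifnot(species_col %in% names(data), class_col %in% names(data))
  cls <- factor(data[[class_col]])
  spraw <- data[[species_col]]
  sp <- as.character(spraw)
  known <- levels(factor(spraw))
  unknown <- !is.na(cls) & (is.na(sp) | !sp %in% known)
  if (any(unknown)) {
    warning(sum(unknown), " pixel(s) with unknown species put in 'other'")
    sp[unknown] <- "other"
  }
  df <- tibble::tibble(species = sp, resilience = cls)
  df <- dplyr::filter(df, !is.na(.data$resilience), !is.na(.data$species))
  df |>
    dplyr::count(.data$species, .data$resilience, name = "n_pixels") |>
    dplyr::mutate(area_ha = .data$n_pixels * cell_size^2 / 1e4) |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(row_share = .data$area_ha / sum(.data$area_ha)) |>
    dplyr::group_by(.data$resilience) |>
    dplyr::mutate(col_share = .data$area_ha / sum(.data$area_ha)) |>
    dplyr::ungroup()
}

#' Resilience composition of severe FVC-loss areas
#'
#' Among pixels whose FVC drop class is at or above `severe_class` (default
#' `"40-60%"`, i.e. a >40% cover decline), the area and share of each
#' resilience class — the cross-tabulation linking defoliation severity to
#' dieback.
#'
#' @param data Pixel tibble.
#' @param drop_col Column of FVC drop classes ([fvc_drop_levels()] labels).
#' @param class_col Column of resilience classes.
#' @param severe_class First drop class counted as severe.
#' @param cell_size Cell edge length, m.
#' @return A tibble: `resilience`, `n_pixels`, `area_ha`, `share`; attribute
#'   `severe_area_ha` gives the total severe area.
#' @export
fvc_loss_by_resilience <- function(data, drop_col = "fvc_drop",
                                   class_col = "resilience",
                                   severe_class = "40-60%",
                                   cell_size = 30) {
  stopifnot(drop_col %in% names(data), class_col %in% names(data))
  lev <- fvc_drop_levels()
  stopifnot(severe_class %in% lev)
  k_min <- match(severe_class, lev)
  k <- match(as.character(data[[drop_col]]), lev)
  severe <- !is.na(k) & k >= k_min
  df <- tibble::tibble(resilience = factor(data[[class_col]])[severe])
  df <- dplyr::filter(df, !is.na(.data$resilience))
  out <- df |>
    dplyr::count(.data$resilience, .drop = FALSE, name = "n_pixels") |>
    dplyr::mutate(
      area_ha = .data$n_pixels * cell_size^2 / 1e4,
      share = if (sum(.data$n_pixels) > 0) {
        .data$n_pixels / sum(.data$n_pixels)
      } else {
        NA_real_
      }
    )
  attr(out, "severe_area_ha") <- sum(out$area_ha)
  out
}
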
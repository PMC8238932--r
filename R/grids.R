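#' Class bin definitions for raster stratification
#'
#' Defines ordered, left-closed/right-open intervals used to stratify
#' continuous rasters (canopy height, wind speed, fractional cover) into the
#' discrete classes used throughout the analysis. With `open_top = TRUE` the
#' last interval is unbounded above (e.g. ">50" m/s winds); with
#' `open_top = FALSE` the last interval is closed at the final edge, so a
#' value exactly at the top edge (e.g. 100% cover) falls in the last class.
#'
#' @param edges Strictly increasing numeric breakpoints.
#' @param labels Character class names, one per interval: `length(edges)`
#'   intervals when `open_top = TRUE`, `length(edges) - 1` otherwise.
#' @param open_top Is the last interval unbounded above?
#' @return An object of class `class_bins`.
#' @examples
#' height_class_bins()
#' bin_values(c(3, 12.3, 27), height_class_bins())
#' @export
class_bins <- function(edges, labels, open_top = TRUE) {
  edges <- as.numeric(edges)
  stopifnot(length(edges) >= 2L, !anyNA(edges))
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  n_int <- if (open_top) length(edges) else length(edges) - 1L
  if (length(labels) != n_int) {
    stop("need ", n_int, " labels for ", n_int, " intervals, got ", length(labels))
  }
  structure(
    list(edges = edges, labels = as.character(labels), open_top = open_top),
    class = "class_bins"
  )
}

#' @export
print.class_bins <- function(x, ...) {
  cat("<class_bins> ", length(x$labels), " classes: ",
      paste(x$labels, collapse = ", "),
      if (x$open_top) " (open top)" else " (closed top)", "\n", sep = "")
  invisible(x)
}

#' Pre-storm canopy height classes (m)
#'
#' Five canopy-height strata: 0-5, 5-10, 10-15, 15-20 and >20 m.
#' @return A [class_bins()] object.
#' @export
height_class_bins <- function() {
  class_bins(c(0, 5, 10, 15, 20),
             c("0-5 m", "5-10 m", "10-15 m", "15-20 m", ">20 m"),
             open_top = TRUE)
}

#' Maximum wind speed classes (m/s)
#'
#' Six 5 m/s storm-wind strata: 26-30, 31-35, 36-40, 41-45, 46-50 and >50.
#' The upper class is treated as open-topped.
#' @return A [class_bins()] object.
#' @export
wind_class_bins <- function() {
  class_bins(c(26, 31, 36, 41, 46, 51),
             c("26-30", "31-35", "36-40", "41-45", "46-50", ">50"),
             open_top = TRUE)
}

#' Fractional vegetation cover classes
#'
#' Five 20%-wide FVC strata on the 0-1 fraction scale. The top interval is
#' closed so that full cover (1.0) falls in "80-100%".
#' @return A [class_bins()] object.
#' @export
fvc_class_bins <- function() {
  class_bins(c(0, 0.2, 0.4, 0.6, 0.8, 1),
             c("0-20%", "20-40%", "40-60%", "60-80%", "80-100%"),
             open_top = FALSE)
}

#' Assign values to classes
#'
#' Bins a numeric vector (or matrix, flattened) into the classes of a
#' [class_bins()] object. Intervals are left-closed/right-open; the top
#' interval is closed when `open_top = FALSE` and unbounded when
#' `open_top = TRUE`, so a value exactly on an interior edge always falls in
#' the upper class. Values below the first edge (or above a closed top) are
#' returned as `NA` with a warning giving the count; `NA` input is preserved.
#'
#' @param x Numeric vector or matrix.
#' @param bins A [class_bins()] object.
#' @return A factor with the bin labels as levels, same length as `x`.
#' @examples
#' bin_values(c(12.3, 10, 4.9), height_class_bins())
#' bin_values(37, wind_class_bins())
#' @export
bin_values <- function(x, bins) {
  stopifnot(inherits(bins, "class_bins"))
  x <- as.numeric(x)
  idx <- findInterval(x, bins$edges, rightmost.closed = !bins$open_top)
  n_int <- length(bins$labels)
  out_of_range <- !is.na(x) & (idx < 1L | idx > n_int)
  if (any(out_of_range)) {
    warning(sum(out_of_range), " value(s) outside the bin range set to NA")
    idx[out_of_range] <- NA_integer_
  }
  idx[idx < 1L | idx > n_int] <- NA_integer_
  factor(bins$labels[idx], levels = bins$labels)
}

#' Storm surge depth above ground
#'
#' Water depth over each pixel: surge water-surface elevation minus ground
#' elevation, clipped at zero (pixels above the water surface are dry).
#' Both inputs must be in the same vertical datum (m asl); `NA` propagates.
#'
#' @param surge_level Water-surface elevation (m asl), vector or matrix.
#' @param elevation Ground elevation (m asl), same shape.
#' @return Surge depth in metres, same shape as the inputs.
#' @examples
#' surge_depth(3.0, 0.1)
#' surge_depth(0.2, 0.5)
#' @export
surge_depth <- function(surge_level, elevation) {
  if (length(surge_level) != length(elevation)) {
    stop("surge_level and elevation must be co-registered (same length)")
  }
  pmax(surge_level - elevation, 0)
}

#' Area covered by a class
#'
#' @param classes Categorical vector (factor or atomic) of per-pixel classes;
#'   `NA` marks nodata.
#' @param class_id The class to measure.
#' @param cell_size Cell edge length in metres.
#' @return Area in hectares (`pixels * cell_size^2 / 1e4`). An unknown class
#'   returns 0 with a warning.
#' @examples
#' area_of(rep(c("a", "b"), c(100, 50)), "a", cell_size = 30)
#' @export
area_of <- function(classes, class_id, cell_size = 30) {
  if (!class_id %in% unique(as.character(classes))) {
    warning("class '", class_id, "' not present; area 0")
    return(0)
  }
  sum(as.character(classes) == class_id, na.rm = TRUE) * cell_size^2 / 1e4
}

#' Per-class pixel counts and areas
#'
#' @inheritParams area_of
#' @return A tibble with `class`, `n_pixels`, `area_ha`; one row per class
#'   present (nodata pixels excluded).
#' @export
class_areas <- function(classes, cell_size = 30) {
  f <- if (is.factor(classes)) classes else factor(classes)
  tb <- table(f)
  tibble::tibble(
    class = names(tb),
    n_pixels = as.integer(tb),
    area_ha = as.integer(tb) * cell_size^2 / 1e4
  )
}

#' Read and write rasters as Esri ASCII grids
#'
#' Single-band rasters are exchanged as Esri ASCII grid (`.asc`) files, a
#' plain-text raster format understood by GDAL, QGIS and ArcGIS. Rows are
#' written north-to-south, matching the package's row-major, origin-top-left
#' grid convention. `NA` is written as the `nodata` value.
#'
#' @param values Numeric matrix (rows = north to south).
#' @param path Output path.
#' @param cell_size Cell edge length in metres.
#' @param nodata Value standing in for `NA` in the file.
#' @param xll,yll Coordinates of the lower-left corner (arbitrary local
#'   datum; the analysis never uses them).
#' @return `write_ascii_grid()` returns `path` invisibly. `read_ascii_grid()`
#'   returns a list with `values` (matrix) and `cell_size`.
#' @export
write_ascii_grid <- function(values, path, cell_size = 30, nodata = -9999,
                             xll = 0, yll = 0) {
  stopifnot(is.matrix(values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    paste("xllcorner", xll),
    paste("yllcorner", yll),
    paste("cellsize", cell_size),
    paste("NODATA_value", nodata)
  ), con)
  vals <- values
  vals[is.na(vals)] <- nodata
  write.table(format(vals, trim = TRUE, digits = 9, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  m <- as.matrix(read.table(path, skip = 6L))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == val[["nrows"]], ncol(m) == val[["ncols"]])
  m[m == val[["nodata_value"]]] <- NA_real_
  list(values = m, cell_size = val[["cellsize"]])
}

#' Resample a raster to a coarser grid
#'
#' Block-resampling between co-registered grids whose resolutions differ by
#' an integer factor: continuous layers are mean-aggregated, categorical
#' layers take the block majority (nearest-equivalent for label data). The
#' default synthetic runs share one grid and never call this; it supports
#' mixed-resolution inputs such as a fine species map on a coarse analysis
#' grid.
#'
#' @param values Matrix to aggregate.
#' @param factor Integer block size (e.g. 30 for 1 m -> 30 m).
#' @param categorical Majority rule instead of block mean?
#' @return The aggregated matrix.
#' @export
resample_block <- function(values, factor, categorical = FALSE) {
  stopifnot(is.matrix(values), factor >= 1, factor == as.integer(factor))
  nr <- nrow(values) %/% factor
  nc <- ncol(values) %/% factor
  out <- matrix(if (categorical) values[1] else NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    rows <- ((i - 1L) * factor + 1L):(i * factor)
    for (j in seq_len(nc)) {
      block <- values[rows, ((j - 1L) * factor + 1L):(j * factor)]
      out[i, j] <- if (categorical) {
        tb <- table(block)
        names(tb)[which.max(tb)]
      } else {
        mean(block, na.rm = TRUE)
      }
    }
  }
  if (!categorical) out[is.nan(out)] <- NA
  out
}
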
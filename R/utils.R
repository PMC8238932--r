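# Internal helpers shared across modules.

# Derive a stage-specific seed from the master seed so that stages are
# independently reproducible. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(
    terrain = 101L, storm = 211L, canopy = 307L, scenes = 401L,
    sample = 503L, classifier = 601L, ks = 701L, pool = 809L
  )
  off <- offsets[[stage]]
  (as.integer(seed) %% 1000000L) * 2011L + off
}

# Gaussian-smoothed white noise on an r x c lattice, standardized to mean 0,
# sd 1. Separable blur with a reflected-edge moving kernel; `range` is the
# kernel sd in cells.
smooth_field <- function(nrow, ncol, range = 8) {
  z <- matrix(rnorm(nrow * ncol), nrow, ncol)
  k <- stats::dnorm(seq(-3 * range, 3 * range), sd = range)
  k <- k / sum(k)
  pad <- (length(k) - 1L) / 2L
  blur1 <- function(m) {
    # reflect rows at the edges, filter columns of m
    idx <- c(rev(seq_len(pad)), seq_len(nrow(m)), nrow(m) + 1L - seq_len(pad))
    mp <- m[pmin(pmax(idx, 1L), nrow(m)), , drop = FALSE]
    out <- stats::filter(mp, k, sides = 2)
    out[pad + seq_len(nrow(m)), , drop = FALSE]
  }
  z <- blur1(z)
  z <- t(blur1(t(z)))
  z <- matrix(as.numeric(z), nrow, ncol)
  (z - mean(z)) / sd(z)
}

# row/col index tibble for an r x c grid, row-major, origin top-left
grid_index <- function(nrow, ncol) {
  tibble::tibble(
    row = rep(seq_len(nrow), times = ncol),
    col = rep(seq_len(ncol), each = nrow)
  )
}

# Convert a pixel-vector (grid column-major order, as produced by as.vector
# on a matrix) back to a matrix
pixels_to_matrix <- function(x, nrow, ncol) {
  matrix(x, nrow = nrow, ncol = ncol)
}

is_date_scalar <- function(x) inherits(x, "Date") && length(x) == 1L && !is.na(x)

as_years <- function(dates, origin = as.Date("2017-01-01")) {
  as.numeric(dates - origin) / 365.25
}

`%||%` <- function(a, b) if (is.null(a)) b else a
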
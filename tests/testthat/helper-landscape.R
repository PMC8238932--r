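# Shared fixtures: a small synthetic landscape generated once per test run,
# plus brute-force oracles used to check vectorized implementations.

small_config <- function(seed = 101, ...) {
  landscape_config(grid_rows = 50, grid_cols = 50, seed = seed, ...)
}

# lazily generated, cached across test files
test_land <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_landscape(small_config())
    cache
  }
})

# KS statistic by direct ECDF evaluation at every observed point
ks_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(fx - fy))
}

# a tiny scene stack built directly from an NDVI matrix (NIR held at 0.4)
stack_from_ndvi <- function(ndvi_mat, dates, valid = NULL, cell_size = 30) {
  n_px <- nrow(ndvi_mat)
  if (is.null(valid)) valid <- matrix(TRUE, n_px, ncol(ndvi_mat))
  nir <- matrix(0.4, n_px, ncol(ndvi_mat))
  red <- nir * (1 - ndvi_mat) / (1 + ndvi_mat)
  side <- ceiling(sqrt(n_px))
  idx <- grid_index_helper(n_px, side)
  scene_stack(as.Date(dates), red, nir, valid, idx, cell_size)
}

grid_index_helper <- function(n_px, side) {
  tibble::tibble(
    row = ((seq_len(n_px) - 1L) %% side) + 1L,
    col = ((seq_len(n_px) - 1L) %/% side) + 1L
  )
}
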
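#' Generate synthetic terrain, hydrology and species zonation
#'
#' Builds the static landscape layers: a smooth ground-elevation surface
#' rising inland from the coast (the grid's bottom edge), low-lying interior
#' basins (3-16 cm asl) enclosed by a berm crest at `berm_height`, a
#' drainage label (`ponded` inside basins, `drained` elsewhere), a mangrove
#' mask excluding the highest upland ground, and a dominant-species map with
#' realistic zonation: *A. germinans* concentrated in the ponded basins,
#' *R. mangle* on the low coastal fringe, *C. erectus* on high ground, and
#' *L. racemosa*/mixed stands elsewhere.
#'
#' @param config A [landscape_config()].
#' @return A tibble with one row per pixel (row-major, origin top-left):
#'   `row`, `col`, `elevation` (m asl), `basin`, `drainage`
#'   (factor drained/ponded), `mangrove` (logical), `species` (factor,
#'   `NA` outside the mangrove mask).
#' @examples
#' terr <- generate_terrain(landscape_config(grid_rows = 30, grid_cols = 30))
#' table(terr$drainage)
#' @export
generate_terrain <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$grid_rows
  nc <- config$grid_cols
  withr::with_seed(stage_seed(config$seed, "terrain"), {
    px <- grid_index(nr, nc)
    # coastal gradient: coast along the bottom (south) edge, rising inland
    inland <- (nr - px$row) / max(nr - 1, 1)
    rough <- as.vector(smooth_field(nr, nc, range = max(3, nr %/% 25)))
    elevation <- pmax(0.15 + 1.3 * inland + 0.25 * rough, 0.01)

    # interior basins: threshold of an independent smooth field, kept away
    # from the grid margin and the coastal strip so basins are enclosed
    basin <- rep(FALSE, nr * nc)
    if (config$basin_fraction > 0) {
      bf <- as.vector(smooth_field(nr, nc, range = max(3, nr %/% 18)))
      interior <- px$row > 2 & px$row < round(0.85 * nr) &
        px$col > 2 & px$col < nc - 2
      cut <- quantile(bf[interior], probs = config$basin_fraction)
      basin <- interior & bf <= cut
      # basin floor: flat, a few cm asl (median near 9-10 cm)
      elevation[basin] <- 0.03 + 0.13 * runif(sum(basin))
      # berm: non-basin pixels within 2 cells of a basin raised to the crest
      bm <- pixels_to_matrix(basin, nr, nc)
      near <- bm
      for (dr in -2:2) for (dc in -2:2) {
        if (dr == 0 && dc == 0) next
        shifted <- matrix(FALSE, nr, nc)
        rs <- seq_len(nr) + dr
        cs <- seq_len(nc) + dc
        ok_r <- rs >= 1 & rs <= nr
        ok_c <- cs >= 1 & cs <= nc
        shifted[which(ok_r), which(ok_c)] <- bm[rs[ok_r], cs[ok_c]]
        near <- near | shifted
      }
      berm <- as.vector(near) & !basin
      elevation[berm] <- pmax(elevation[berm],
                              config$berm_height + 0.1 + 0.1 * runif(sum(berm)))
    }

    drainage <- factor(ifelse(basin, "ponded", "drained"),
                       levels = c("drained", "ponded"))

    # mangrove mask: everything below the upland fringe
    upland_cut <- quantile(elevation[!basin], probs = 0.90)
    mangrove <- basin | elevation <= upland_cut

    # species zonation
    sp_noise <- as.vector(smooth_field(nr, nc, range = max(3, nr %/% 20)))
    species <- rep("mixed", nr * nc)
    species[sp_noise > 0.3] <- "L. racemosa"
    species[!basin & inland < 0.18 & elevation < 0.6] <- "R. mangle"
    species[!basin & elevation > 0.95] <- "C. erectus"
    u_sp <- runif(nr * nc)
    species[basin & u_sp < 0.9] <- "A. germinans"
    species[!mangrove] <- NA
    species <- factor(species, levels = species_levels())

    tibble::tibble(
      row = px$row, col = px$col,
      elevation = elevation, basin = basin, drainage = drainage,
      mangrove = mangrove, species = species
    )
  })
}

#' Generate storm surge and maximum wind fields
#'
#' The surge water surface is highest (near `surge_amplitude`) along the
#' coast and decays smoothly inland without dropping below ~55% of the
#' amplitude, emulating surge that overtops coastal berms and floods interior
#' basins. Maximum winds span `wind_range` as a smooth west-east gradient
#' with local texture, so every pixel bins into one of the six 5 m/s storm
#' wind classes.
#'
#' @param config A [landscape_config()].
#' @param terrain Pixel tibble from [generate_terrain()].
#' @return `terrain` with columns `surge_level` (water-surface elevation,
#'   m asl) and `max_wind` (m/s) appended.
#' @export
generate_storm_fields <- function(config, terrain) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$grid_rows
  nc <- config$grid_cols
  if (nrow(terrain) != nr * nc) {
    stop("terrain is not on the configured grid")
  }
  withr::with_seed(stage_seed(config$seed, "storm"), {
    inland <- (nr - terrain$row) / max(nr - 1, 1)
    s_noise <- as.vector(smooth_field(nr, nc, range = max(3, nr %/% 15)))
    surge_level <- config$surge_amplitude *
      (0.55 + 0.45 * exp(-3 * inland)) + 0.05 * s_noise * config$surge_amplitude
    if (config$surge_amplitude == 0) surge_level <- rep(0, nr * nc)

    w0 <- config$wind_range[1]
    w1 <- config$wind_range[2]
    w_noise <- as.vector(smooth_field(nr, nc, range = max(3, nr %/% 15)))
    max_wind <- w0 + (w1 - w0) * (1 - (terrain$col - 1) / max(nc - 1, 1)) +
      1.5 * w_noise
    max_wind <- pmin(pmax(max_wind, w0), w1)

    dplyr::mutate(terrain, surge_level = surge_level, max_wind = max_wind)
  })
}
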
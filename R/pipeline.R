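#' Pipeline configuration
#'
#' Bundles the stage configurations of the full analysis chain. One master
#' `seed` governs every stochastic stage: it is threaded into the landscape
#' generator and deterministic stage-specific seeds are derived from it for
#' sampling, classification and the KS resampling.
#'
#' @param seed Master integer seed applied across stages.
#' @param landscape A [landscape_config()].
#' @param composites A [composite_config()].
#' @param thresholds A [resilience_thresholds()].
#' @param ks A [ks_config()].
#' @param classifier A [classifier_spec()]. The default uses 100 trees for
#'   the wall-to-wall FVC mapping: with only a handful of spectral features,
#'   a deeper ensemble is needed to resolve the rarer cover classes.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42,
                            landscape = landscape_config(seed = seed),
                            composites = composite_config(),
                            thresholds = resilience_thresholds(),
                            ks = ks_config(seed = seed),
                            classifier = classifier_spec(n_trees = 100,
                                                         seed = seed)) {
  stopifnot(inherits(landscape, "landscape_config"),
            inherits(composites, "composite_config"),
            inherits(thresholds, "resilience_thresholds"),
            inherits(ks, "ks_config"),
            inherits(classifier, "classifier_spec"))
  structure(list(seed = as.integer(seed), landscape = landscape,
                 composites = composites, thresholds = thresholds,
                 ks = ks, classifier = classifier),
            class = "pipeline_config")
}

#' Run the full damage-and-resilience pipeline
#'
#' Orchestrates every stage on a synthetic landscape: generation, stereo-DSM
#' bias correction and canopy volume change, height/wind damage summaries
#' with ANOVA/Tukey, FVC classification and class-change mapping with an
#' accuracy assessment, NDVI-anomaly resilience classification, exposure
#' attribution, and the iterated KS comparison. When `outdir` is given,
#' every product is written (rasters as Esri ASCII grids, tables as CSV)
#' together with a JSON manifest listing each artifact with its MD5
#' checksum; re-running with the same configuration reproduces the
#' checksums. Stage progress is logged to `stderr`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @param quiet Suppress progress logging?
#' @return (Invisibly) a list with the landscape, every stage result, the
#'   summary tibbles and, when written, the `manifest` tibble.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[resilmap] ", ...)
  t0 <- Sys.time()
  cell <- config$landscape$cell_size

  say("generating synthetic landscape (",
      config$landscape$grid_rows, "x", config$landscape$grid_cols, ")")
  land <- simulate_landscape(config$landscape)
  px <- land$pixels

  say("canopy: bias correction, volume, damage summary")
  bc <- fit_bias_correction(px, "dsm_pre", "chm_pre", mask = "mangrove",
                            n = 1000, seed = stage_seed(config$seed, "sample"))
  px$chm_stereo <- apply_bias_correction(px$dsm_pre, bc)
  vol_pre <- canopy_volume(px$chm_pre, px$mangrove, cell)
  vol_post <- canopy_volume(px$chm_post, px$mangrove, cell)
  dmg <- damage_summary(px, mask = "mangrove", cell_size = cell)
  loss_df <- dplyr::mutate(
    dplyr::filter(px, .data$mangrove),
    loss = .data$chm_pre - .data$chm_post,
    height_class = bin_values(.data$chm_pre, height_class_bins())
  )
  aov_res <- anova_tukey(loss_df, "loss", "height_class")

  say("cover: FVC classification and change mapping")
  pre_comp <- median_composite(land$scenes, config$composites$pre_window)
  post_comp <- median_composite(land$scenes, config$composites$post_window)
  feats <- c("red", "nir", "ndvi")
  # one classifier per epoch, each trained on that epoch's lidar FVC classes
  train_epoch <- function(comp, labels) {
    df <- dplyr::bind_cols(comp[, feats], label = labels)
    train_cover_classifier(df, feats, "label", config$classifier)
  }
  clf_pre <- train_epoch(pre_comp, px$true_fvc_class_pre)
  clf_post <- train_epoch(post_comp, px$true_fvc_class_post)
  fvc_pred_pre <- predict_cover(clf_pre, pre_comp)
  fvc_pred_post <- predict_cover(clf_post, post_comp)
  px$fvc_drop <- fvc_change(fvc_pred_pre, fvc_pred_post)
  em <- error_matrix(fvc_pred_pre, px$true_fvc_class_pre, n_per_class = 500,
                     seed = stage_seed(config$seed, "sample"))

  say("resilience: composites, anomalies, recovery times, classes")
  res <- assess_resilience(land$scenes, config$composites, config$thresholds,
                           mask = px$mangrove)
  px <- dplyr::bind_cols(
    px, res[, c("ndvi_ref", "mean_anomaly", "drop", "slope",
                "recovery_time", "recovered", "resilience")]
  )
  px$surge_depth <- surge_depth(px$surge_level, px$elevation)

  say("attribution: elevation, surge, species, FVC loss")
  mang <- dplyr::filter(px, .data$mangrove)
  dist_elev <- class_distribution(mang, "resilience", "elevation",
                                  bin_width = 0.01, cell_size = cell)
  dist_surge <- class_distribution(mang, "resilience", "surge_depth",
                                   bin_width = 0.1, cell_size = cell)
  exceed_low <- exceedance_fraction(mang, "resilience", "surge_depth",
                                    "low", 1.4)
  species_tab <- area_by_species(mang, cell_size = cell)
  fvc_tab <- fvc_loss_by_resilience(mang, cell_size = cell)

  say("stats: iterated KS comparison (", config$ks$iterations, " iterations)")
  mang <- dplyr::mutate(
    mang,
    height_loss = .data$chm_pre - .data$chm_post,
    pct_height_loss = percent_height_loss(.data$chm_pre, .data$chm_post)
  )
  ks_vars <- c("chm_pre", "height_loss", "pct_height_loss", "elevation",
               "surge_depth")
  ks_rep <- iterated_ks(mang, "resilience", ks_vars, config$ks)

  out <- list(
    config = config, landscape = land, pixels = px,
    bias_correction = bc,
    volume = tibble::tibble(
      volume_pre_m3 = vol_pre, volume_post_m3 = vol_post,
      volume_loss_pct = 100 * (vol_pre - vol_post) / vol_pre
    ),
    damage_summary = dmg, anova = aov_res,
    fvc_classifier = list(pre = clf_pre, post = clf_post),
    error_matrix = em,
    resilience = res,
    distributions = list(elevation = dist_elev, surge_depth = dist_surge),
    exceedance_low_1p4m = exceed_low,
    area_by_species = species_tab,
    fvc_loss_by_resilience = fvc_tab,
    ks_report = ks_rep
  )

  if (!is.null(outdir)) {
    say("writing products and manifest to ", outdir)
    out$manifest <- write_pipeline_outputs(out, outdir)
  }
  say("done in ", round(as.numeric(Sys.time() - t0, units = "secs"), 1), " s")
  invisible(out)
}

# Serialize pipeline products: ASCII-grid rasters, CSV tables, JSON manifest
# with MD5 checksums.
write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- out$config$landscape
  nr <- cfg$grid_rows
  nc <- cfg$grid_cols
  px <- out$pixels
  path <- function(f) file.path(outdir, f)

  grid_of <- function(x) pixels_to_matrix(x, nr, nc)
  write_ascii_grid(grid_of(px$elevation), path("elevation.asc"),
                   cfg$cell_size)
  write_ascii_grid(grid_of(px$chm_pre), path("chm_pre.asc"), cfg$cell_size)
  write_ascii_grid(grid_of(px$chm_post), path("chm_post.asc"), cfg$cell_size)
  write_ascii_grid(grid_of(px$surge_depth), path("surge_depth.asc"),
                   cfg$cell_size)
  # categorical products as documented integer codes
  write_ascii_grid(grid_of(as.integer(px$resilience)),
                   path("resilience.asc"), cfg$cell_size)
  write_ascii_grid(grid_of(as.integer(px$fvc_drop) - 1L),
                   path("fvc_drop.asc"), cfg$cell_size)

  write.csv(out$damage_summary, path("damage_summary.csv"),
            row.names = FALSE)
  write.csv(out$anova$letters, path("anova_letters.csv"), row.names = FALSE)
  write.csv(out$volume, path("canopy_volume.csv"), row.names = FALSE)
  write.csv(as.data.frame(out$error_matrix$counts),
            path("fvc_error_matrix.csv"), row.names = FALSE)
  write.csv(out$distributions$elevation$summary,
            path("elevation_by_class.csv"), row.names = FALSE)
  write.csv(out$distributions$surge_depth$cdf,
            path("surge_cdf_by_class.csv"), row.names = FALSE)
  write.csv(out$area_by_species, path("area_by_species.csv"),
            row.names = FALSE)
  write.csv(out$fvc_loss_by_resilience, path("fvc_loss_by_resilience.csv"),
            row.names = FALSE)
  write.csv(out$ks_report, path("ks_report.csv"), row.names = FALSE)

  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- tibble::tibble(
    file = files,
    bytes = file.size(file.path(outdir, files)),
    md5 = unname(tools::md5sum(file.path(outdir, files)))
  )
  legend <- list(
    resilience = c(`1` = "low", `2` = "intermediate", `3` = "high"),
    fvc_drop = setNames(fvc_drop_levels(), 0:4)
  )
  jsonlite::write_json(
    list(seed = out$config$seed,
         grid = c(rows = nr, cols = nc, cell_size = cfg$cell_size),
         legend = legend, files = manifest),
    path("manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest
}
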
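test_that("the generator is deterministic given a seed", {
  cfg <- landscape_config(grid_rows = 25, grid_cols = 25, seed = 9,
                          revisit_days = 48)
  a <- simulate_landscape(cfg)
  b <- simulate_landscape(cfg)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$scenes$red, b$scenes$red)
  expect_identical(a$scenes$valid, b$scenes$valid)
  c_ <- simulate_landscape(landscape_config(grid_rows = 25, grid_cols = 25,
                                            seed = 10, revisit_days = 48))
  expect_false(identical(a$pixels$elevation, c_$pixels$elevation))
})

test_that("terrain realizes the configured basin structure", {
  cfg0 <- small_config(basin_fraction = 0)
  t0 <- generate_terrain(cfg0)
  expect_true(all(t0$drainage == "drained"))

  terr <- test_land()$pixels
  frac <- mean(terr$drainage == "ponded")
  expect_lt(abs(frac - 0.3), 0.1)
  # ponded basins sit below the enclosing berm crest
  expect_true(all(terr$elevation[terr$drainage == "ponded"] <
                    small_config()$berm_height))
  # basin specialist concentrated in basins
  pond_ag <- mean(terr$species[terr$drainage == "ponded"] == "A. germinans",
                  na.rm = TRUE)
  drain_ag <- mean(terr$species[terr$drainage == "drained"] == "A. germinans",
                   na.rm = TRUE)
  expect_gt(pond_ag, 0.5)
  expect_gt(pond_ag, drain_ag)
  expect_error(landscape_config(grid_rows = 0), "positive")
})

test_that("storm fields span the configured ranges and flood the basins", {
  px <- test_land()$pixels
  # every wind value falls in one of the six storm classes
  wc <- bin_values(px$max_wind, wind_class_bins())
  expect_false(anyNA(wc))
  expect_equal(sort(unique(as.character(wc))),
               sort(wind_class_bins()$labels))
  # zero surge -> zero depth everywhere
  s0 <- generate_storm_fields(small_config(surge_amplitude = 0),
                              generate_terrain(small_config()))
  expect_true(all(surge_depth(s0$surge_level, s0$elevation) == 0))
  # the deepest basin pixel floods deeper than the berm crest
  depth <- surge_depth(px$surge_level, px$elevation)
  crest <- px$elevation >= small_config()$berm_height & !px$basin
  expect_gt(max(depth[px$basin]), max(depth[crest]))
})

test_that("wind damage increases with pre-storm canopy height", {
  px <- test_land()$pixels
  expect_true(all(px$true_height_loss >= 0))
  expect_true(all(px$chm_post >= 0))
  hc <- bin_values(px$chm_pre, height_class_bins())
  m <- tapply(px$true_height_loss, hc, mean)
  expect_gt(m[["10-15 m"]], m[["0-5 m"]])
  expect_gt(m[["15-20 m"]], m[["0-5 m"]])
  expect_gt(cor(px$chm_pre, px$true_height_loss, method = "spearman"), 0)
  # cover can only be lost
  expect_true(all(px$fvc_post <= px$fvc_pre + 1e-12))
  expect_true(all(px$fvc_pre >= 0 & px$fvc_pre <= 1))
})

test_that("noise-free identity DSM equals the canopy height model", {
  cfg <- small_config(dsm_intercept = 0, dsm_slope = 1, dsm_noise_sd = 0)
  px <- generate_canopy(cfg, generate_storm_fields(cfg, generate_terrain(cfg)))
  expect_equal(px$dsm_pre, px$chm_pre, tolerance = 1e-12)
})

test_that("reflectance series realize the class NDVI trajectories", {
  land <- test_land()
  v <- ndvi_matrix(land$scenes)
  expect_true(all(v >= -1 & v <= 1))
  # all-clear sky when cloud_prob = 0
  cfg0 <- landscape_config(grid_rows = 20, grid_cols = 20, cloud_prob = 0,
                           revisit_days = 64)
  l0 <- simulate_landscape(cfg0)
  expect_true(all(l0$scenes$valid))

  # low-resilience pixels: 15-month mean anomaly below -0.2, computed
  # directly from the generated series against the generating reference
  px <- land$pixels
  cols <- which(land$scenes$dates >= as.Date("2017-09-17"))
  low <- which(!is.na(px$true_resilience) & px$true_resilience == "low")
  anom <- rowMeans(v[low, cols, drop = FALSE] - px$ndvi_ref_true[low])
  expect_lt(mean(anom), -0.2)
  expect_gt(mean(anom < -0.2), 0.95)
})

test_that("truth classes have separated NDVI-drop distributions", {
  px <- test_land()$pixels
  drops <- split(px$ndvi_drop_true[!is.na(px$true_resilience)],
                 px$true_resilience[!is.na(px$true_resilience)])
  for (pair in list(c("low", "intermediate"), c("low", "high"),
                    c("intermediate", "high"))) {
    d <- ks_statistic(drops[[pair[1]]], drops[[pair[2]]])
    expect_gt(d, ks_critical(length(drops[[pair[1]]]),
                             length(drops[[pair[2]]])))
  }
})

test_that("configuration invariants are enforced", {
  expect_error(landscape_config(basin_fraction = 1.4))
  expect_error(landscape_config(cloud_prob = 1))
  expect_error(landscape_config(revisit_days = 0))
  expect_error(landscape_config(storm_date = "2019-01-01"),
               "series_start < storm_date")
})
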
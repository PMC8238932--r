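test_that("bias correction recovers an exact identity", {
  px <- tibble::tibble(chm = runif(1500, 0, 20))
  px$dsm <- px$chm
  bc <- fit_bias_correction(px, "dsm", "chm", seed = 3)
  expect_equal(bc$slope, 1, tolerance = 1e-9)
  expect_equal(bc$intercept, 0, tolerance = 1e-9)
  expect_lt(bc$rmse, 1e-9)
})

test_that("bias correction recovers generator parameters within its CI", {
  withr::with_seed(11, {
    px <- tibble::tibble(chm = runif(5000, 0, 20))
    px$dsm <- 2 + 0.9 * px$chm + rnorm(5000, sd = 0.1)
  })
  bc <- fit_bias_correction(px, "dsm", "chm", n = 1000, seed = 4)
  # invert: chm = -a/b + (1/b) dsm
  expect_equal(bc$slope, 1 / 0.9, tolerance = 0.05)
  expect_equal(bc$intercept, -2 / 0.9, tolerance = 0.1)
  expect_true(bias_correction_covers(bc, -2 / 0.9, 1 / 0.9))
  td <- tidy(bc)
  expect_equal(td$term, c("intercept", "slope"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  expect_equal(glance(bc)$n_samples, 1000)
})

test_that("bias correction rejects degenerate input and warns when short", {
  px <- tibble::tibble(dsm = rep(5, 100), chm = runif(100))
  expect_error(fit_bias_correction(px, "dsm", "chm", n = 50, seed = 1),
               "degenerate")
  px2 <- tibble::tibble(dsm = runif(40), chm = runif(40))
  expect_warning(bc <- fit_bias_correction(px2, "dsm", "chm", n = 1000,
                                           seed = 1),
                 "using all")
  expect_equal(bc$n_samples, 40)
  expect_error(fit_bias_correction(px2[0, ], "dsm", "chm"), "at least 2")
})

test_that("applying a correction is affine with a zero clip", {
  bc <- list(intercept = 2, slope = 0.9)
  expect_equal(apply_bias_correction(10, bc), 11)
  expect_equal(apply_bias_correction(c(0, -10), list(intercept = 0.5,
                                                     slope = 1)),
               c(0.5, 0))
  expect_equal(apply_bias_correction(-5, list(intercept = 2, slope = 1)), 0)
})

test_that("canopy volume sums height times cell area and is linear", {
  expect_equal(canopy_volume(rep(10, 100), cell_size = 1), 1000)
  expect_equal(canopy_volume(runif(10), mask = rep(FALSE, 10)), 0)
  px <- test_land()$pixels
  v_pre <- canopy_volume(px$chm_pre, px$mangrove, 30)
  v_post <- canopy_volume(px$chm_post, px$mangrove, 30)
  v_loss <- canopy_volume(px$chm_pre - px$chm_post, px$mangrove, 30)
  expect_equal(v_pre - v_post, v_loss, tolerance = 1e-9)
})

test_that("damage summary matches a per-pixel group-by oracle", {
  px <- test_land()$pixels
  ds <- damage_summary(px, mask = "mangrove")
  m <- px[px$mangrove, ]
  oracle <- tibble::tibble(
    loss = m$chm_pre - m$chm_post,
    h = bin_values(m$chm_pre, height_class_bins()),
    w = bin_values(m$max_wind, wind_class_bins())
  )
  for (i in seq_len(nrow(ds))) {
    sel <- oracle$loss[oracle$h == ds$height_class[i] &
                         oracle$w == ds$wind_class[i]]
    expect_equal(ds$mean_loss_m[i], mean(sel), tolerance = 1e-9)
    expect_equal(ds$se_m[i], sd(sel) / sqrt(length(sel)), tolerance = 1e-9)
    expect_equal(ds$n_pixels[i], length(sel))
  }
  # stratified areas partition the mask
  expect_equal(sum(ds$area_ha), sum(px$mangrove) * 900 / 1e4)
  # constant loss: every populated row has mean 2, SE 0
  px2 <- tibble::tibble(chm_pre = runif(200, 0, 24),
                        max_wind = runif(200, 26, 54))
  px2$chm_post <- px2$chm_pre - 2
  ds2 <- damage_summary(px2)
  expect_true(all(abs(ds2$mean_loss_m - 2) < 1e-12))
  expect_true(all(ds2$se_m < 1e-12))
})

test_that("taller height classes lose more canopy on the synthetic coast", {
  ds <- damage_summary(test_land()$pixels, mask = "mangrove")
  agg <- tapply(ds$mean_loss_m * ds$n_pixels, ds$height_class, sum) /
    tapply(ds$n_pixels, ds$height_class, sum)
  expect_gt(agg[["10-15 m"]], agg[["0-5 m"]])
})

test_that("anova_tukey flags separated groups and not identical ones", {
  withr::with_seed(21, {
    df <- tibble::tibble(
      g = rep(c("a", "b"), each = 50),
      y = rnorm(100, sd = 1) + rep(c(0, 10), each = 50)
    )
  })
  res <- anova_tukey(df, "y", "g")
  expect_lt(res$p_value, 1e-6)
  expect_true(all(res$pairs$significant))
  expect_false(res$letters$letters[1] == res$letters$letters[2])

  # same values in every group: F is 0, no pair differs, one shared letter
  df2 <- tibble::tibble(g = rep(c("a", "b", "c"), each = 3),
                        y = rep(c(1, 2, 3), times = 3))
  res2 <- anova_tukey(df2, "y", "g")
  expect_equal(res2$f_statistic, 0, tolerance = 1e-12)
  expect_false(any(res2$pairs$significant))
  expect_equal(length(unique(res2$letters$letters)), 1L)

  # zero variance everywhere: degenerate F reported without error
  df3 <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = rep(1, 6))
  res3 <- anova_tukey(df3, "y", "g")
  expect_false(is.finite(res3$f_statistic) && res3$f_statistic > 0)
  expect_false(any(res3$pairs$significant))

  expect_error(anova_tukey(df2[df2$g == "a", ], "y", "g"), "2 groups")
  expect_error(anova_tukey(df2[c(1, 4), ], "y", "g"), "2 samples")
})

test_that("compact letters mirror the non-significance graph", {
  # three groups: a/b indistinguishable, b/c indistinguishable, a/c distinct
  withr::with_seed(8, {
    df <- tibble::tibble(
      g = rep(c("a", "b", "c"), each = 25),
      y = rnorm(75, mean = rep(c(0, 0.75, 1.5), each = 25), sd = 1)
    )
  })
  res <- anova_tukey(df, "y", "g")
  lt <- setNames(res$letters$letters, as.character(res$letters$group))
  shares <- function(p, q) {
    any(strsplit(lt[[p]], "")[[1]] %in% strsplit(lt[[q]], "")[[1]])
  }
  for (i in seq_len(nrow(res$pairs))) {
    expect_equal(
      shares(res$pairs$group_a[i], res$pairs$group_b[i]),
      !res$pairs$significant[i]
    )
  }
})
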
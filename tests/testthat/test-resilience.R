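test_that("normalized difference indices follow the ratio arithmetic", {
  expect_equal(ndvi(0.4, 0.1), 0.6)
  expect_equal(ndvi(0.3, 0.3), 0)
  expect_equal(ndvi(0.4, 0), 1)
  expect_true(is.na(ndvi(0.2, -0.2)))
  expect_equal(ndwi(0.1, 0.4), -0.6)
  m <- matrix(runif(20, 0.01, 0.6), 4, 5)
  expect_true(all(ndvi(m, m * 0.5) >= -1 & ndvi(m, m * 0.5) <= 1))
})

test_that("median composites use only valid observations", {
  dates <- as.Date("2016-01-01") + c(0, 30, 60)
  st <- stack_from_ndvi(rbind(c(0.2, 0.8, 0.5), c(0.4, 0.4, 0.4)), dates)
  comp <- median_composite(st, range(dates))
  expect_equal(comp$ndvi, c(0.5, 0.4))
  # invalid observations are excluded
  st2 <- stack_from_ndvi(rbind(c(0.2, 0.9, 0.9)), dates,
                         valid = matrix(c(TRUE, FALSE, FALSE), 1))
  comp2 <- median_composite(st2, range(dates))
  expect_equal(comp2$ndvi, 0.2)
  expect_equal(comp2$n_obs, 1L)
  # a pixel with no valid observation is nodata
  st3 <- stack_from_ndvi(rbind(c(0.2, 0.3, 0.4)), dates,
                         valid = matrix(FALSE, 1, 3))
  expect_true(is.na(median_composite(st3, range(dates))$ndvi))
  expect_warning(median_composite(st, c("2030-01-01", "2030-02-01")),
                 "no scenes")
})

test_that("composites, anomalies and slopes match per-pixel oracles", {
  withr::with_seed(51, {
    n_px <- 100 # 10 x 10 grid
    dates <- as.Date("2018-01-05") + seq(0, 350, by = 25)
    v <- matrix(runif(n_px * length(dates), 0.1, 0.9), n_px)
    valid <- matrix(runif(n_px * length(dates)) > 0.3, n_px)
    valid[1, ] <- c(TRUE, rep(FALSE, length(dates) - 1)) # 1 obs
    valid[2, ] <- FALSE                                  # 0 obs
    ref <- runif(n_px, 0.3, 0.8)
  })
  st <- stack_from_ndvi(v, dates, valid)
  win <- range(dates)

  comp <- median_composite(st, win)
  anom <- mean_anomaly(st, ref, win)
  slp <- ndvi_slope(st, win)
  t_yr <- as.numeric(dates - as.Date("2017-01-01")) / 365.25
  t_end <- as.numeric(win[2] - as.Date("2017-01-01")) / 365.25

  for (i in seq_len(n_px)) {
    vv <- v[i, valid[i, ]]
    tt <- t_yr[valid[i, ]]
    if (length(vv) == 0) {
      expect_true(is.na(comp$ndvi[i]) && is.na(anom$mean_anomaly[i]))
    } else {
      expect_equal(comp$ndvi[i], median(vv), tolerance = 1e-9)
      expect_equal(anom$mean_anomaly[i], mean(vv - ref[i]), tolerance = 1e-9)
    }
    if (length(vv) >= 2) {
      fit <- lm(vv ~ tt)
      expect_equal(slp$slope[i], unname(coef(fit)[2]), tolerance = 1e-9)
      expect_equal(slp$ndvi_fit_end[i],
                   unname(coef(fit)[1] + coef(fit)[2] * t_end),
                   tolerance = 1e-9)
    } else {
      expect_true(is.na(slp$slope[i]))
    }
  }
})

test_that("a noiseless linear NDVI ramp yields its exact slope", {
  dates <- as.Date("2018-01-01") + seq(0, 360, by = 30)
  t_yr <- as.numeric(dates - dates[1]) / 365.25
  st <- stack_from_ndvi(rbind(0.3 + 0.05 * t_yr, rep(0.4, length(dates))),
                        dates)
  slp <- ndvi_slope(st, range(dates))
  expect_equal(slp$slope, c(0.05, 0), tolerance = 1e-9)
})

test_that("mean anomaly of a series against itself is zero", {
  land <- test_land()
  pre_win <- c("2015-08-31", "2017-08-31")
  comp <- median_composite(land$scenes, pre_win)
  anom <- mean_anomaly(land$scenes, comp$ndvi, pre_win)
  noise <- land$config$noise_sd_reflectance
  expect_lt(abs(mean(anom$mean_anomaly, na.rm = TRUE)), noise)
})

test_that("recovery time extrapolates the fitted deficit", {
  expect_equal(recovery_time(0.15, 0.03), 5.0)
  expect_equal(recovery_time(-0.02, 0.03), 0)
  expect_equal(recovery_time(0, 0.03), 0)
  expect_true(is.na(recovery_time(0.15, -0.01)))
  expect_true(is.na(recovery_time(0.15, 0)))
  expect_equal(recovery_time(c(0.3, -1, 0.1), c(0.1, 0.2, -0.5)),
               c(3, 0, NA))
})

test_that("the three-tier rules classify the canonical cases", {
  # large drop with browning trend: dieback
  expect_equal(as.character(resilience_class(0.25, -0.005, NA, FALSE)),
               "low")
  # fast predicted recovery pre-empts the drop rule
  expect_equal(as.character(resilience_class(0.3, 0.1, 3, FALSE)), "high")
  # moderate drop, 5-15 yr recovery
  expect_equal(as.character(resilience_class(0.15, 0.02, 9, FALSE)),
               "intermediate")
  # small drop despite storm winds
  expect_equal(as.character(resilience_class(0.05, -0.01, NA, FALSE)),
               "high")
  # observed recovery wins regardless of everything else
  expect_equal(as.character(resilience_class(0.35, -0.1, NA, TRUE)), "high")
  # moderate drop with stalled trend stays intermediate, not low
  expect_equal(as.character(resilience_class(0.15, -0.01, NA, FALSE)),
               "intermediate")
  # large drop but recovery just inside the slow bound
  expect_equal(as.character(resilience_class(0.25, 0.02, 12, FALSE)),
               "intermediate")
  expect_true(is.na(resilience_class(NA, 0.1, 3, FALSE)))
})

test_that("classification is total and mutually exclusive", {
  grid <- expand.grid(
    drop = seq(-0.05, 0.4, by = 0.05),
    slope = c(-0.02, 0, 0.005, 0.05),
    recovered = c(TRUE, FALSE)
  )
  grid$recovery_time <- recovery_time(grid$drop * 0.9, grid$slope)
  cls <- resilience_class(grid$drop, grid$slope, grid$recovery_time,
                          grid$recovered)
  expect_false(anyNA(cls))
  expect_true(all(cls %in% resilience_levels()))
  # the same inputs through the data-frame interface agree
  df <- tibble::tibble(mean_anomaly = -grid$drop, slope = grid$slope,
                       recovery_time = grid$recovery_time,
                       recovered = grid$recovered)
  expect_equal(classify_resilience(df)$resilience, cls)
})

test_that("composite window validation names the offending field", {
  expect_error(composite_config(pre_window = "2015-08-31"), "pre_window")
  expect_error(composite_config(post_window = c("2017-12-31", "2017-10-01")),
               "post_window")
  expect_error(
    composite_config(pre_window = c("2015-08-31", "2017-11-30")),
    "pre_window must end"
  )
})
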
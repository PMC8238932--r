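test_that("FVC class change maps reductions to 20%-wide drop bins", {
  # worked example: 80-100% before, 20-40% after = 3 classes lost -> 40-60%
  expect_equal(as.character(fvc_change(5, 2)), "40-60%")
  expect_equal(as.character(fvc_change("80-100%", "20-40%")), "40-60%")
  expect_equal(as.character(fvc_change(3, 3)), "none")
  expect_equal(as.character(fvc_change(2, 5)), "none") # greening clipped
  expect_true(is.na(fvc_change(6, 2)))
  expect_true(is.na(fvc_change(2, 0)))
  expect_error(fvc_change(1:3, 1:2), "co-registered")
})

test_that("FVC change equals the 25-entry lookup oracle", {
  lookup <- matrix(NA_character_, 5, 5)
  for (pre in 1:5) {
    for (post in 1:5) {
      k <- max(pre - post, 0)
      lookup[pre, post] <- fvc_drop_levels()[k + 1]
    }
  }
  grid <- expand.grid(pre = 1:5, post = 1:5)
  got <- as.character(fvc_change(grid$pre, grid$post))
  expect_equal(got, lookup[cbind(grid$pre, grid$post)])
})

test_that("a separable feature is classified perfectly by both backends", {
  withr::with_seed(31, {
    df <- tibble::tibble(band = runif(3000))
    df$label <- cut(df$band, c(0, 0.25, 0.5, 0.75, 1),
                    labels = paste0("c", 1:4), include.lowest = TRUE)
    df$other <- rnorm(3000)
  })
  for (kind in c("nearest-centroid", "random-forest")) {
    clf <- train_cover_classifier(
      df, c("band", "other"), "label",
      classifier_spec(kind, n_train_per_class = 300, seed = 5)
    )
    pred <- predict_cover(clf, df)
    expect_gt(mean(pred == df$label), if (kind == "random-forest") 0.97
              else 0.85)
  }
})

test_that("classification is seed-deterministic and feature-checked", {
  withr::with_seed(32, {
    df <- tibble::tibble(a = rnorm(800), b = rnorm(800),
                         label = sample(c("x", "y"), 800, TRUE))
  })
  spec <- classifier_spec("random-forest", n_train_per_class = 200, seed = 7)
  expect_no_warning(c1 <- train_cover_classifier(df, c("a", "b"), "label",
                                                 spec))
  c2 <- train_cover_classifier(df, c("a", "b"), "label", spec)
  expect_identical(predict_cover(c1, df), predict_cover(c2, df))
  expect_error(predict_cover(c1, df[, "label"]), "absent")
  # all-missing features give all-NA predictions
  na_df <- tibble::tibble(a = NA_real_, b = NA_real_)
  expect_true(all(is.na(predict_cover(c1, na_df))))
})

test_that("permuted labels drop holdout accuracy to chance", {
  accs <- withr::with_seed(33, {
    n <- 4000
    df <- tibble::tibble(band = runif(n))
    df$label <- cut(df$band, c(0, 0.25, 0.5, 0.75, 1),
                    labels = paste0("c", 1:4), include.lowest = TRUE)
    holdout <- df[2001:n, ]
    vapply(1:10, function(i) {
      train <- df[1:2000, ]
      train$label <- sample(train$label)
      clf <- train_cover_classifier(
        train, "band", "label",
        classifier_spec("nearest-centroid", n_train_per_class = 400,
                        seed = i)
      )
      mean(predict_cover(clf, holdout) == holdout$label)
    }, numeric(1))
  })
  expect_lt(abs(mean(accs) - 0.25), 0.1)
})

test_that("the wall-to-wall FVC map recovers truth classes on the coast", {
  land <- test_land()
  px <- land$pixels
  comp <- median_composite(land$scenes, c("2015-08-31", "2017-08-31"))
  df <- dplyr::bind_cols(comp[, c("red", "nir", "ndvi")],
                         label = px$true_fvc_class_pre)
  withr::with_seed(41, idx <- sample.int(nrow(df), 1500))
  suppressWarnings({
    clf <- train_cover_classifier(
      df[-idx, ], c("red", "nir", "ndvi"), "label",
      classifier_spec("nearest-centroid", n_train_per_class = 400, seed = 6)
    )
  })
  acc <- mean(as.character(predict_cover(clf, df[idx, ])) ==
                as.character(df$label[idx]), na.rm = TRUE)
  expect_gt(acc, 0.8)
})

test_that("the error matrix scores agreement on stratified samples", {
  withr::with_seed(35, ref <- sample(c("m", "n"), 5000, TRUE))
  em <- error_matrix(ref, ref, n_per_class = 500, seed = 1)
  expect_equal(em$overall_accuracy, 1.0)
  expect_equal(em$n, 1000)

  em2 <- error_matrix(rep("m", 5000), ref, n_per_class = 500, seed = 1)
  expect_equal(em2$overall_accuracy, 0.5)

  withr::with_seed(36, {
    a <- sample(paste0("c", 1:4), 20000, TRUE)
    b <- sample(paste0("c", 1:4), 20000, TRUE)
  })
  em3 <- error_matrix(a, b, n_per_class = 500, seed = 2)
  expect_lt(abs(em3$overall_accuracy - 0.25), 0.05)
  expect_equal(glance(em3)$n, 2000)
  expect_equal(sum(tidy(em3)$n), 2000)

  w <- testthat::capture_warnings(
    error_matrix(ref[1:100], ref[1:100], n_per_class = 500)
  )
  expect_true(any(grepl("using all", w)))
})
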
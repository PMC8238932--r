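#' Classifier specification for wall-to-wall cover mapping
#'
#' Settings for the supervised classifier that scales lidar-derived class
#' labels (FVC classes, or mangrove extent) to wall-to-wall maps from
#' reflectance composites. The default is a random forest with 20 trees and
#' a bag fraction of 0.5 trained on 1000 stratified points per class;
#' `kind = "nearest-centroid"` selects a deterministic centroid classifier
#' useful as a library-independent reference.
#'
#' @param kind `"random-forest"` or `"nearest-centroid"`.
#' @param n_trees Number of trees (random forest only).
#' @param bag_fraction Fraction of the training set bagged per tree.
#' @param n_train_per_class Training points sampled per class.
#' @param seed Integer seed for sampling and tree growing.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("random-forest", "nearest-centroid"),
                            n_trees = 20, bag_fraction = 0.5,
                            n_train_per_class = 1000, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n_trees >= 1, bag_fraction > 0, bag_fraction <= 1,
            n_train_per_class >= 1)
  structure(list(kind = kind, n_trees = as.integer(n_trees),
                 bag_fraction = bag_fraction,
                 n_train_per_class = as.integer(n_train_per_class),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train a cover classifier on stratified samples
#'
#' Draws a seeded stratified sample (`n_train_per_class` pixels per present
#' class, without replacement; classes with fewer pixels contribute all of
#' them with a warning) and fits the classifier named in `spec` to the given
#' feature columns. Pixels with `NA` in the label or any feature are
#' excluded from the sampling frame.
#'
#' @param data Pixel tibble.
#' @param features Character vector of feature column names (e.g. composite
#'   bands and indices).
#' @param labels Column name of the class labels (factor or coercible).
#' @param spec A [classifier_spec()].
#' @return An object of class `cover_classifier`.
#' @export
train_cover_classifier <- function(data, features, labels,
                                   spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"),
            all(features %in% names(data)), labels %in% names(data))
  y <- factor(data[[labels]])
  x <- as.data.frame(data[, features])
  ok <- !is.na(y) & complete.cases(x)
  present <- levels(droplevels(y[ok]))
  if (length(present) < 2L) stop("need at least 2 classes with valid pixels")

  idx <- withr::with_seed(spec$seed, {
    unlist(lapply(present, function(cl) {
      pool <- which(ok & y == cl)
      if (length(pool) < spec$n_train_per_class) {
        warning("class '", cl, "' has only ", length(pool),
                " pixels; using all")
        pool
      } else {
        sample(pool, spec$n_train_per_class)
      }
    }))
  })
  xt <- x[idx, , drop = FALSE]
  yt <- droplevels(y[idx])

  # zero-variance predictors carry no signal and degrade random split
  # selection; drop them up front
  keep_feat <- vapply(xt, function(col) sd(col) > 0, logical(1))
  if (!all(keep_feat)) {
    warning("dropping constant feature(s): ",
            paste(features[!keep_feat], collapse = ", "))
    if (!any(keep_feat)) stop("all features are constant")
    features <- features[keep_feat]
    xt <- xt[, keep_feat, drop = FALSE]
  }

  model <- switch(
    spec$kind,
    "nearest-centroid" = {
      mu <- vapply(xt, mean, numeric(1))
      sg <- vapply(xt, sd, numeric(1))
      sg[sg == 0 | is.na(sg)] <- 1
      xs <- scale(as.matrix(xt), center = mu, scale = sg)
      centroids <- do.call(rbind, lapply(levels(yt), function(cl) {
        colMeans(xs[yt == cl, , drop = FALSE])
      }))
      rownames(centroids) <- levels(yt)
      list(centroids = centroids, center = mu, scale = sg)
    },
    "random-forest" = withr::with_seed(spec$seed, {
      randomForest::randomForest(
        x = xt, y = yt, ntree = spec$n_trees,
        sampsize = ceiling(spec$bag_fraction * nrow(xt)), replace = TRUE
      )
    })
  )
  structure(
    list(kind = spec$kind, model = model, features = features,
         levels = levels(yt), spec = spec, n_train = nrow(xt)),
    class = "cover_classifier"
  )
}

#' @export
print.cover_classifier <- function(x, ...) {
  cat("<cover_classifier> ", x$kind, ", ", length(x$levels), " classes (",
      paste(x$levels, collapse = ", "), "), ", x$n_train,
      " training points\n", sep = "")
  invisible(x)
}

#' Predict cover classes for a feature table
#'
#' Applies a trained [train_cover_classifier()] model to a pixel table with
#' the same feature columns. Pixels with any missing feature are `NA`.
#'
#' @param classifier A `cover_classifier`.
#' @param data Pixel tibble carrying the classifier's feature columns.
#' @return Factor of predicted classes, one per row of `data`.
#' @export
predict_cover <- function(classifier, data) {
  stopifnot(inherits(classifier, "cover_classifier"))
  missing <- setdiff(classifier$features, names(data))
  if (length(missing)) {
    stop("feature columns absent from data: ", paste(missing, collapse = ", "))
  }
  x <- as.data.frame(data[, classifier$features])
  ok <- complete.cases(x)
  out <- factor(rep(NA_character_, nrow(x)), levels = classifier$levels)
  if (!any(ok)) return(out)
  pred <- switch(
    classifier$kind,
    "nearest-centroid" = {
      m <- classifier$model
      xs <- scale(as.matrix(x[ok, , drop = FALSE]),
                  center = m$center, scale = m$scale)
      d2 <- outer(rowSums(xs^2), rowSums(m$centroids^2), "+") -
        2 * xs %*% t(m$centroids)
      rownames(m$centroids)[max.col(-d2, ties.method = "first")]
    },
    # vote ties in randomForest are broken with the RNG; pin it so repeated
    # prediction is reproducible
    "random-forest" = withr::with_seed(classifier$spec$seed, as.character(
      predict(classifier$model, newdata = x[ok, , drop = FALSE])
    ))
  )
  out[ok] <- pred
  out
}

#' FVC drop class labels
#'
#' Labels of the FVC class-change product: `"none"` for no class reduction,
#' then 20%-wide drop intervals for reductions of 1-4 classes.
#' @return Character vector of the five drop labels.
#' @export
fvc_drop_levels <- function() {
  c("none", "0-20%", "20-40%", "40-60%", "60-80%")
}

#' Map FVC class change to drop classes
#'
#' Converts pre- and post-storm five-class FVC rasters into the FVC-drop
#' product. A reduction of `k` classes maps to the `k`-th 20%-wide drop
#' interval (`k = 3`, e.g. 80-100% down to 20-40%, gives a drop of 40-60%);
#' no reduction (including apparent greening, clipped to 0) is `"none"`.
#' Codes outside 1..5 give `NA`.
#'
#' @param pre,post FVC classes: factors with the [fvc_class_bins()] labels,
#'   or integer codes 1-5.
#' @return Factor with [fvc_drop_levels()] levels, same length.
#' @examples
#' fvc_change(5, 2) # three-class reduction -> "40-60%"
#' @export
fvc_change <- function(pre, post) {
  to_code <- function(z) {
    if (is.factor(z) || is.character(z)) {
      as.integer(factor(as.character(z), levels = fvc_class_bins()$labels))
    } else {
      z <- as.integer(z)
      z[!is.na(z) & (z < 1L | z > 5L)] <- NA_integer_
      z
    }
  }
  p1 <- to_code(pre)
  p2 <- to_code(post)
  if (length(p1) != length(p2)) stop("pre and post must be co-registered")
  k <- pmax(p1 - p2, 0L)
  factor(fvc_drop_levels()[k + 1L], levels = fvc_drop_levels())
}

#' Accuracy assessment against a reference map
#'
#' Draws a seeded stratified sample (`n_per_class` pixels per class present
#' in the reference; all pixels with a warning when a class is smaller) and
#' cross-tabulates predictions against the reference to form the error
#' matrix and its overall accuracy (trace over total).
#'
#' @param predicted,reference Categorical vectors on one grid.
#' @param n_per_class Sample size per reference class.
#' @param seed Integer seed.
#' @return An object of class `error_matrix`: `counts` (reference in rows,
#'   prediction in columns), `overall_accuracy`, `n`.
#' @export
error_matrix <- function(predicted, reference, n_per_class = 500, seed = 1) {
  if (length(predicted) != length(reference)) {
    stop("predicted and reference must be co-registered")
  }
  ref <- factor(reference)
  prd <- factor(as.character(predicted))
  ok <- !is.na(ref) & !is.na(prd)
  classes <- levels(droplevels(ref[ok]))
  idx <- withr::with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      pool <- which(ok & ref == cl)
      if (length(pool) < n_per_class) {
        warning("reference class '", cl, "' has only ", length(pool),
                " pixels; using all")
        pool
      } else {
        sample(pool, n_per_class)
      }
    }))
  })
  lev <- union(classes, levels(droplevels(prd[idx])))
  counts <- table(
    reference = factor(as.character(ref[idx]), levels = lev),
    predicted = factor(as.character(prd[idx]), levels = lev)
  )
  structure(
    list(counts = counts,
         overall_accuracy = sum(diag(counts)) / sum(counts),
         n = sum(counts)),
    class = "error_matrix"
  )
}

#' @export
print.error_matrix <- function(x, ...) {
  cat("<error_matrix> overall accuracy ",
      round(100 * x$overall_accuracy, 1), "% on ", x$n, " points\n", sep = "")
  print(x$counts)
  invisible(x)
}
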
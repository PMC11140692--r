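#' Assemble a training set from a labelled scene
#'
#' Samples pixels per class from the truth raster among rows with complete
#' features. Defaults follow the study design floors: at least 100 samples
#' per class, at least 550 in total (a warning is raised if a class cannot
#' meet the floor).
#'
#' @param features feature matrix from [scene_features()].
#' @param class_raster truth [cg_raster] of class codes 1..6.
#' @param n_per_class samples drawn per class.
#' @param min_per_class,min_total invariant floors (warn when violated).
#' @param seed RNG seed.
#' @return list with `x` (feature matrix), `y` (factor of class labels),
#'   `cells` (sampled cell indices).
#' @export
make_training_set <- function(features, class_raster, n_per_class = 100,
                              min_per_class = 100, min_total = 550,
                              seed = 1L) {
  cls <- as.integer(class_raster$values)
  ok <- attr(features, "ok")
  cells <- with_seed(seed, {
    unlist(lapply(seq_along(scene_classes()), function(k) {
      pool <- which(cls == k & ok)
      if (!length(pool)) stop("class with zero usable samples: ",
                              scene_classes()[k], call. = FALSE)
      sample(pool, min(n_per_class, length(pool)))
    }))
  })
  y <- factor(scene_classes()[cls[cells]], levels = scene_classes())
  if (any(table(y) < min_per_class) || length(y) < min_total) {
    warning(sprintf(
      "training set below design floors (>= %d per class, >= %d total)",
      min_per_class, min_total))
  }
  list(x = features[cells, , drop = FALSE], y = y, cells = cells)
}

#' Train the tree-ensemble classifier
#'
#' A bagged ensemble of decision trees: each tree is grown on a bootstrap
#' sample with a random feature subset considered at every split, and
#' prediction is by majority vote (ties broken towards the lowest class
#' index). Deterministic for a fixed seed.
#'
#' @param train list with `x` (features) and `y` (factor labels), as from
#'   [make_training_set()].
#' @param n_trees trees in the ensemble.
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param seed RNG seed.
#' @return a `cg_classifier` wrapping the fitted forest.
#' @export
train_classifier <- function(train, n_trees = 500,
                             mtry = max(1, floor(sqrt(ncol(train$x)))),
                             seed = 1L) {
  y <- droplevels(factor(train$y))
  if (nlevels(y) < 2) {
    stop("training set must contain at least two classes", call. = FALSE)
  }
  rf <- with_seed(seed, {
    randomForest::randomForest(x = train$x, y = y, ntree = n_trees,
                               mtry = mtry)
  })
  structure(list(forest = rf, features = colnames(train$x),
                 classes = levels(y), n_trees = n_trees, seed = seed),
            class = "cg_classifier")
}

#' @export
print.cg_classifier <- function(x, ...) {
  cat(sprintf("<cg_classifier> %d trees, %d features, OOB error %.2f%%\n",
              x$n_trees, length(x$features),
              100 * x$forest$err.rate[x$n_trees, "OOB"]))
  invisible(x)
}

#' Out-of-bag error of a trained classifier
#' @param model a `cg_classifier`.
#' @return OOB error rate in `[0,1]`.
#' @export
oob_error <- function(model) {
  unname(model$forest$err.rate[model$n_trees, "OOB"])
}

#' Predict a class map from feature rasters
#'
#' Labels every pixel with complete features; `NA` feature rows propagate
#' to no-data pixels. The feature column order must match training.
#'
#' @param model a [train_classifier()] result.
#' @param features feature matrix from [scene_features()].
#' @param template a [cg_raster] providing the grid (e.g. the truth raster).
#' @return a `classified_map`: `class_raster` (integer codes into
#'   `model$classes`), `binary` (1 = cordgrass, 0 = other, NA = no data),
#'   `pixel_size`, `classes`.
#' @export
predict_map <- function(model, features, template) {
  if (!identical(colnames(features), model$features)) {
    stop("feature bands do not match the training bands", call. = FALSE)
  }
  ok <- attr(features, "ok")
  if (is.null(ok)) ok <- stats::complete.cases(features)
  pred <- rep(NA_integer_, nrow(features))
  if (any(ok)) {
    p <- stats::predict(model$forest, features[ok, , drop = FALSE])
    pred[ok] <- as.integer(p)
  }
  labels <- model$classes[pred]
  binary <- ifelse(is.na(labels), NA_real_,
                   as.numeric(labels == "spartina"))
  structure(
    list(class_raster = raster_like(template, pred),
         binary = raster_like(template, binary),
         classes = model$classes,
         pixel_size = template$pixel_size),
    class = "classified_map"
  )
}

#' @export
print.classified_map <- function(x, ...) {
  v <- raster_values(x$binary)
  cat(sprintf(
    "<classified_map> %d pixels (%d no-data); cordgrass fraction %.1f%%\n",
    length(v), sum(is.na(v)), 100 * mean(v, na.rm = TRUE)))
  invisible(x)
}

#' Stratified validation sample from a classified map
#'
#' Uniform random sampling without replacement within the cordgrass and
#' non-cordgrass strata (default 150 / 300 points).
#'
#' @param map a [predict_map()] result.
#' @param n_sa,n_non points per stratum.
#' @param seed RNG seed.
#' @return data.frame `(cell, x, y, stratum)` with stratum
#'   `"spartina"`/`"non_spartina"`.
#' @export
stratified_validation_sample <- function(map, n_sa = 150, n_non = 300,
                                         seed = 1L) {
  bin <- raster_values(map$binary)
  sa_pool <- which(!is.na(bin) & bin == 1)
  non_pool <- which(!is.na(bin) & bin == 0)
  if (length(sa_pool) < n_sa) {
    stop(sprintf("cordgrass stratum has only %d pixels (%d requested)",
                 length(sa_pool), n_sa), call. = FALSE)
  }
  if (length(non_pool) < n_non) {
    stop(sprintf("non-cordgrass stratum has only %d pixels (%d requested)",
                 length(non_pool), n_non), call. = FALSE)
  }
  cells <- with_seed(seed, {
    c(if (length(sa_pool) == n_sa) sa_pool else sample(sa_pool, n_sa),
      if (length(non_pool) == n_non) non_pool else sample(non_pool, n_non))
  })
  xy <- cell_xy(map$binary, cells)
  data.frame(cell = cells, x = xy$x, y = xy$y,
             stratum = rep(c("spartina", "non_spartina"), c(n_sa, n_non)))
}

#' Confusion matrix and accuracy statistics
#'
#' Computes overall accuracy (OA), per-class producer's accuracy (PA,
#' recall conditioned on the reference), user's accuracy (UA, precision
#' conditioned on the prediction) and the kappa coefficient
#' `(p_o - p_e) / (1 - p_e)` with chance agreement `p_e` from the marginal
#' products. Percentages are reported to 2 decimals.
#'
#' @param reference,predicted paired label vectors (factors or characters).
#' @return a `confusion_matrix`: `table` (reference x predicted counts),
#'   `oa`, `pa`, `ua` (percent, 2 dp), `kappa` (full precision).
#' @export
confusion_metrics <- function(reference, predicted) {
  if (!length(reference) || length(reference) != length(predicted)) {
    stop("reference and predicted labels must be non-empty and paired",
         call. = FALSE)
  }
  lev <- union(unique(as.character(reference)), unique(as.character(predicted)))
  ref <- factor(as.character(reference), levels = lev)
  prd <- factor(as.character(predicted), levels = lev)
  tab <- table(reference = ref, predicted = prd)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  pa <- diag(tab) / rowSums(tab) * 100
  ua <- diag(tab) / colSums(tab) * 100
  structure(
    list(table = tab, oa = round(100 * po, 2),
         pa = round(pa, 2), ua = round(ua, 2), kappa = kappa,
         n = n),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$table)
  cat(sprintf("OA = %.2f%%   kappa = %.4f\n", x$oa, x$kappa))
  for (cl in names(x$pa)) {
    cat(sprintf("  %-14s PA = %6.2f%%  UA = %6.2f%%\n", cl, x$pa[cl], x$ua[cl]))
  }
  invisible(x)
}

#' Binary accuracy of a classified map against a truth raster
#'
#' Collapses the six classes to cordgrass / non-cordgrass and evaluates
#' over all pixels with data (or a supplied subset of cells).
#'
#' @param map a [predict_map()] result.
#' @param class_raster truth class codes.
#' @param cells optional cell subset (e.g. a validation sample).
#' @return a [confusion_metrics()] result.
#' @export
map_accuracy <- function(map, class_raster, cells = NULL) {
  truth <- as.integer(class_raster$values) == 1L
  bin <- raster_values(map$binary)
  keep <- !is.na(bin)
  idx <- which(keep)
  if (!is.null(cells)) idx <- intersect(cells, idx)
  lab <- function(z) ifelse(z, "spartina", "non_spartina")
  confusion_metrics(lab(truth[idx]), lab(bin[idx] == 1))
}
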
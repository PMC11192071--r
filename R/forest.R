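#' Bootstrapped decision-tree ensemble classifier
#'
#' A random-forest style classifier: `n_trees` CART trees with axis-aligned
#' threshold splits chosen by Gini impurity decrease, each grown on a
#' bootstrap resample (n draws with replacement) of the training pixels,
#' considering a random subset of `mtry` features at every node. Prediction
#' is by majority vote with ties broken toward the lowest class index.
#' Growing and prediction run in compiled code with a self-contained RNG,
#' so a seed fully determines the forest.
#'
#' @param train A [training_set()].
#' @param bands Band subset to fit on (default all).
#' @param n_trees Number of trees (default 500).
#' @param mtry Features considered per split (default `floor(sqrt(bands))`).
#' @param min_node Minimum node size before splitting stops (default 1).
#' @param seed Integer seed.
#' @return An object of class `forest_model`.
#' @export
fit_rf <- function(train, bands = NULL, n_trees = 500L, mtry = NULL,
                   min_node = 1L, seed = 1L) {
  stopifnot(inherits(train, "training_set"), n_trees >= 1)
  X <- train$spectra
  if (!is.null(bands)) {
    idx <- if (is.character(bands)) match(bands, colnames(X)) else bands
    X <- X[, idx, drop = FALSE]
  }
  classes <- levels(droplevels(train$class))
  y <- match(as.character(droplevels(train$class)), classes) - 1L
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- .cpp_forest_fit(X, as.integer(y), length(classes),
                           as.integer(n_trees), as.integer(mtry),
                           as.integer(min_node), as.numeric(seed))
  structure(list(classes = classes, bands = colnames(X), trees = trees,
                 n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 min_node = as.integer(min_node), seed = as.integer(seed)),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("<forest_model> %d trees, mtry %d, %d classes on %d bands\n",
              x$n_trees, x$mtry, length(x$classes), length(x$bands)))
  invisible(x)
}

forest_votes <- function(model, X) {
  v <- .cpp_forest_votes(model$trees, X, length(model$classes))
  colnames(v) <- model$classes
  v
}

#' Predict land cover with a tree-ensemble model
#'
#' @inheritParams predict_mlc
#' @param model A `forest_model` from [fit_rf()].
#' @return A [classified_raster()]; the "posterior" grids hold vote shares.
#' @export
predict_rf <- function(model, raster, probs = TRUE) {
  predict_raster_engine(raster, model$bands, model$classes, "rf",
                        function(X) {
                          v <- forest_votes(model, X)
                          list(label = max.col(v, ties.method = "first"),
                               prob = v / model$n_trees)
                        }, probs = probs)
}

#' @rdname classify_matrix_mlc
#' @export
classify_matrix_rf <- function(model, X) {
  X <- align_bands(X, model$bands)
  v <- forest_votes(model, X)
  lab <- max.col(v, ties.method = "first")
  list(label = lab, class = model$classes[lab], prob = v / model$n_trees)
}
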
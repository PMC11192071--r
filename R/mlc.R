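#' Gaussian maximum-likelihood classifier
#'
#' The classical parametric land-cover classifier: each class is modelled
#' as a multivariate Gaussian with its own mean and covariance estimated
#' from the training spectra, and a pixel `x` is assigned to the class
#' maximizing the Bayes discriminant
#' `g_c(x) = ln pi_c - 1/2 ln|S_c| - 1/2 (x - mu_c)' S_c^{-1} (x - mu_c)`.
#' Covariances get a small ridge (`ridge x mean diagonal`) so that they stay
#' invertible for thin classes.
#'
#' @param train A [training_set()].
#' @param bands Band subset to fit on (names or indices; default all).
#' @param priors `"uniform"` (default), `"frequency"`, or a named numeric
#'   vector summing to 1.
#' @param ridge Relative ridge added to covariance diagonals
#'   (default `1e-6`).
#' @return An object of class `mlc_model`.
#' @export
fit_mlc <- function(train, bands = NULL, priors = "uniform", ridge = 1e-6) {
  stopifnot(inherits(train, "training_set"))
  X <- train$spectra
  if (!is.null(bands)) {
    idx <- if (is.character(bands)) match(bands, colnames(X)) else bands
    X <- X[, idx, drop = FALSE]
  }
  classes <- levels(droplevels(train$class))
  p <- ncol(X)
  means <- list(); covs <- list(); logdets <- numeric(); chols <- list()
  for (cl in classes) {
    Xc <- X[train$class == cl, , drop = FALSE]
    if (nrow(Xc) <= p) {
      warning("class ", cl, " has ", nrow(Xc), " samples for ", p,
              " bands; covariance relies on the ridge")
    }
    mu <- colMeans(Xc)
    S <- if (nrow(Xc) > 1) cov(Xc) else diag(p)
    S <- S + diag(ridge * mean(diag(S)) + 1e-12, p)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) {
      stop("covariance of class ", cl, " is singular even after ridge")
    }
    means[[cl]] <- mu
    covs[[cl]] <- S
    chols[[cl]] <- ch
    logdets[cl] <- 2 * sum(log(diag(ch)))
  }
  pr <- if (identical(priors, "uniform")) {
    rep(1 / length(classes), length(classes))
  } else if (identical(priors, "frequency")) {
    as.numeric(table(droplevels(train$class))[classes]) / nrow(X)
  } else {
    stopifnot(abs(sum(priors) - 1) < 1e-8)
    as.numeric(priors[classes])
  }
  names(pr) <- classes
  structure(list(classes = classes, bands = colnames(X), means = means,
                 covariances = covs, chol = chols, logdet = logdets,
                 priors = pr, ridge = ridge),
            class = "mlc_model")
}

#' @export
print.mlc_model <- function(x, ...) {
  cat(sprintf("<mlc_model> %d classes on %d bands (%s)\n",
              length(x$classes), length(x$bands),
              paste(head(x$bands, 3), collapse = ", ")))
  invisible(x)
}

# discriminant matrix (pixels x classes) for a spectra matrix
mlc_discriminants <- function(model, X) {
  n <- nrow(X)
  G <- matrix(NA_real_, n, length(model$classes))
  for (j in seq_along(model$classes)) {
    cl <- model$classes[j]
    ctr <- X - matrix(model$means[[cl]], n, ncol(X), byrow = TRUE)
    # Mahalanobis quadratic form via the Cholesky factor
    z <- backsolve(model$chol[[cl]], t(ctr), transpose = TRUE)
    q <- colSums(z^2)
    G[, j] <- log(model$priors[[cl]]) - 0.5 * model$logdet[[cl]] - 0.5 * q
  }
  colnames(G) <- model$classes
  G
}

softmax_rows <- function(G) {
  m <- apply(G, 1, max)
  E <- exp(G - m)
  E / rowSums(E)
}

#' Classified raster
#'
#' Output container of all three classifiers: an integer label grid (`NA`
#' where any input band was nodata), the class list, optional per-class
#' posterior/score grids (each summing to 1 per classified pixel), and
#' provenance.
#'
#' @param labels Integer matrix of class indices (`NA` = unclassified).
#' @param classes Character class list.
#' @param posterior Optional `nrow x ncol x nclass` array.
#' @param model_id Character tag of the producing model.
#' @param bands Bands the model consumed.
#' @inheritParams multiband_raster
#' @return An object of class `classified_raster`.
#' @export
classified_raster <- function(labels, classes, pixel_size, origin,
                              crs = "EPSG:32712", posterior = NULL,
                              model_id = "unknown", bands = character()) {
  lr <- label_raster(labels, classes, pixel_size, origin, crs)
  structure(c(unclass(lr),
              list(posterior = posterior, model_id = model_id, bands = bands)),
            class = c("classified_raster", "label_raster"))
}

# shared predict plumbing: pull the model's bands out of the raster,
# classify the valid pixels, and fold back into grids
predict_raster_engine <- function(raster, model_bands, classes, model_id,
                                  classify_fun, probs = TRUE) {
  idx <- match(model_bands, raster$band_names)
  if (anyNA(idx)) {
    stop("raster lacks bands required by the model: ",
         paste(model_bands[is.na(idx)], collapse = ", "))
  }
  X <- raster_to_matrix(raster)[, idx, drop = FALSE]
  d <- dim(raster)
  valid <- !is.na(X[, 1])
  out <- rep(NA_integer_, nrow(X))
  post <- NULL
  if (any(valid)) {
    res <- classify_fun(X[valid, , drop = FALSE])
    out[valid] <- res$label
    if (probs && !is.null(res$prob)) {
      post <- array(NA_real_, c(d[1], d[2], length(classes)))
      for (k in seq_along(classes)) {
        layer <- rep(NA_real_, nrow(X))
        layer[valid] <- res$prob[, k]
        post[, , k] <- matrix_to_layer(layer, d[1], d[2])
      }
    }
  }
  classified_raster(matrix_to_layer(out, d[1], d[2]), classes,
                    raster$pixel_size, raster$origin, raster$crs,
                    posterior = post, model_id = model_id,
                    bands = model_bands)
}

#' Predict land cover with a maximum-likelihood model
#'
#' Assigns each valid pixel the class with the largest Bayes discriminant;
#' per-class posteriors are the softmax of the discriminants. Ties break to
#' the lowest class index. Nodata pixels stay unclassified.
#'
#' @param model An `mlc_model` from [fit_mlc()].
#' @param raster A [multiband_raster()] containing the model's bands.
#' @param probs Keep posterior grids (default `TRUE`).
#' @return A [classified_raster()].
#' @export
predict_mlc <- function(model, raster, probs = TRUE) {
  predict_raster_engine(raster, model$bands, model$classes, "mlc",
                        function(X) {
                          G <- mlc_discriminants(model, X)
                          list(label = max.col(G, ties.method = "first"),
                               prob = softmax_rows(G))
                        }, probs = probs)
}

#' Classify a spectra matrix with a maximum-likelihood model
#'
#' Matrix-level interface used by the split-sample evaluation harness.
#'
#' @param model An `mlc_model`.
#' @param X Pixel x band matrix (bands matching the model, by name if named).
#' @return A list with `label` (integer class indices into `model$classes`),
#'   `class` (character) and `prob` (pixel x class posterior matrix).
#' @export
classify_matrix_mlc <- function(model, X) {
  X <- align_bands(X, model$bands)
  G <- mlc_discriminants(model, X)
  lab <- max.col(G, ties.method = "first")
  list(label = lab, class = model$classes[lab], prob = softmax_rows(G))
}

align_bands <- function(X, bands) {
  X <- as.matrix(X)
  if (!is.null(colnames(X))) {
    idx <- match(bands, colnames(X))
    if (anyNA(idx)) stop("spectra lack bands: ",
                         paste(bands[is.na(idx)], collapse = ", "))
    X <- X[, idx, drop = FALSE]
  } else if (ncol(X) != length(bands)) {
    stop("spectra have ", ncol(X), " bands, model expects ", length(bands))
  }
  X
}
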
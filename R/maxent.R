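#' Maximum-entropy (multinomial logistic) classifier
#'
#' The maximum-entropy principle applied to supervised pixel labelling:
#' among all class-probability models consistent with the feature
#' expectations of the training data, choose the least-informative one.
#' With linear band features this is exactly multinomial logistic
#' regression; we fit the L2-penalized multinomial log-likelihood on
#' per-band z-scored features by damped Newton iteration. With the penalty
#' `lambda` applied to the whole weight matrix (intercepts included), the
#' large-`lambda` limit is the uniform distribution over classes, matching
#' the maximum-entropy reading of "no information".
#'
#' @param train A [training_set()].
#' @param bands Band subset to fit on (default all).
#' @param lambda L2 penalty (default `1e-4`).
#' @param tol Convergence tolerance on the max-norm of the penalized
#'   mean-log-likelihood gradient (default `1e-8`).
#' @param max_iter Maximum Newton iterations (default 500); if exceeded, a
#'   warning is emitted and the best iterate returned.
#' @return An object of class `maxent_model` with the weight matrix
#'   (classes x (1 + bands), on the z-scored scale), the standardization
#'   statistics, and a convergence report.
#' @export
fit_maxent <- function(train, bands = NULL, lambda = 1e-4, tol = 1e-8,
                       max_iter = 500L) {
  stopifnot(inherits(train, "training_set"))
  X <- train$spectra
  if (!is.null(bands)) {
    idx <- if (is.character(bands)) match(bands, colnames(X)) else bands
    X <- X[, idx, drop = FALSE]
  }
  classes <- levels(droplevels(train$class))
  K <- length(classes)
  if (K < 2L) stop("maximum entropy needs at least 2 classes")
  y <- match(as.character(droplevels(train$class)), classes)
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Z <- cbind(1, sweep(sweep(X, 2, ctr), 2, scl, "/"))
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1

  W <- matrix(0, K, p + 1L)
  obj <- function(W) {
    G <- Z %*% t(W)
    m <- apply(G, 1, max)
    ll <- sum(G[cbind(seq_len(n), y)]) - sum(m + log(rowSums(exp(G - m))))
    -ll / n + lambda / 2 * sum(W^2)
  }
  grad_P <- function(W) {
    G <- Z %*% t(W)
    P <- softmax_rows(G)
    list(g = t(P - Y) %*% Z / n + lambda * W, P = P)
  }
  f <- obj(W)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    gp <- grad_P(W)
    g <- gp$g
    if (max(abs(g)) <= tol) { converged <- TRUE; break }
    P <- gp$P
    # full Newton system over the K(p+1) weights
    d <- p + 1L
    H <- matrix(0, K * d, K * d)
    for (a in seq_len(K)) {
      for (b in a:K) {
        wab <- P[, a] * ((a == b) - P[, b])
        Hab <- crossprod(Z, Z * wab) / n
        ra <- (a - 1L) * d + seq_len(d)
        rb <- (b - 1L) * d + seq_len(d)
        H[ra, rb] <- Hab
        if (a != b) H[rb, ra] <- Hab
      }
    }
    H <- H + diag(lambda + 1e-10, K * d)
    step <- tryCatch(solve(H, as.vector(t(g))),
                     error = function(e) as.vector(t(g)))
    Wstep <- matrix(step, K, d, byrow = TRUE)
    # backtracking line search on the penalized objective
    alpha <- 1
    repeat {
      Wnew <- W - alpha * Wstep
      fnew <- obj(Wnew)
      if (fnew <= f - 1e-4 * alpha * sum(g * Wstep) || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    if (fnew >= f - 1e-15 && alpha < 1e-8) break
    W <- Wnew
    f <- fnew
  }
  if (!converged) {
    g <- grad_P(W)$g
    converged <- max(abs(g)) <= tol
    if (!converged) {
      warning("maxent did not reach gradient tolerance ", tol, " within ",
              max_iter, " iterations (|grad|_max = ",
              format(max(abs(g))), "); returning best iterate")
    }
  }
  dimnames(W) <- list(classes, c("(Intercept)", colnames(X)))
  structure(list(classes = classes, bands = colnames(X), weights = W,
                 center = ctr, scale = scl, lambda = lambda,
                 converged = converged, iterations = iters,
                 final_objective = f),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d classes on %d bands; %s in %d iter\n",
              length(x$classes), length(x$bands),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

# class-probability matrix for a spectra matrix
maxent_probs <- function(model, X) {
  Z <- cbind(1, sweep(sweep(X, 2, model$center), 2, model$scale, "/"))
  softmax_rows(Z %*% t(model$weights))
}

#' Penalized mean log-likelihood objective of a maxent model
#'
#' Exposed so that the fitted optimum can be verified against
#' finite-difference gradients.
#'
#' @param model A `maxent_model`.
#' @param train The training set it was fitted on.
#' @param W Optional alternative weight matrix.
#' @return Scalar objective value (negative mean log-likelihood + penalty).
#' @export
maxent_objective <- function(model, train, W = model$weights) {
  X <- align_bands(train$spectra, model$bands)
  y <- match(as.character(train$class), model$classes)
  Z <- cbind(1, sweep(sweep(X, 2, model$center), 2, model$scale, "/"))
  G <- Z %*% t(W)
  m <- apply(G, 1, max)
  ll <- sum(G[cbind(seq_along(y), y)]) - sum(m + log(rowSums(exp(G - m))))
  -ll / nrow(X) + model$lambda / 2 * sum(W^2)
}

#' Predict land cover with a maximum-entropy model
#'
#' @inheritParams predict_mlc
#' @param model A `maxent_model` from [fit_maxent()].
#' @return A [classified_raster()]; per-pixel class probabilities sum to 1.
#' @export
predict_maxent <- function(model, raster, probs = TRUE) {
  predict_raster_engine(raster, model$bands, model$classes, "maxent",
                        function(X) {
                          P <- maxent_probs(model, X)
                          list(label = max.col(P, ties.method = "first"),
                               prob = P)
                        }, probs = probs)
}

#' @rdname classify_matrix_mlc
#' @export
classify_matrix_maxent <- function(model, X) {
  X <- align_bands(X, model$bands)
  P <- maxent_probs(model, X)
  lab <- max.col(P, ties.method = "first")
  list(label = lab, class = model$classes[lab], prob = P)
}
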
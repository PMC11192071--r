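#' Save and load fitted classifier models as JSON
#'
#' All three model types (`mlc_model`, `maxent_model`, `forest_model`)
#' serialize to plain JSON: means/covariances, weight matrices, or flat
#' tree-node tables. Loading restores a model that predicts identically.
#'
#' @param model A fitted model.
#' @param path Output `.json` path.
#' @export
save_model <- function(model, path) {
  type <- class(model)[1]
  obj <- switch(type,
    mlc_model = list(
      type = type, classes = model$classes, bands = model$bands,
      priors = model$priors, ridge = model$ridge,
      means = model$means,
      covariances = lapply(model$covariances, unname)
    ),
    maxent_model = list(
      type = type, classes = model$classes, bands = model$bands,
      weights = unname(model$weights), center = model$center,
      scale = model$scale, lambda = model$lambda,
      converged = model$converged, iterations = model$iterations
    ),
    forest_model = list(
      type = type, classes = model$classes, bands = model$bands,
      n_trees = model$n_trees, mtry = model$mtry,
      min_node = model$min_node, seed = model$seed,
      trees = lapply(model$trees, function(tr) {
        list(nodes = unname(tr$nodes), thr = tr$thr)
      })
    ),
    stop("unknown model type: ", type)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the restored model object.
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  if (obj$type == "mlc_model") {
    covs <- lapply(obj$covariances, function(S) {
      S <- as.matrix(S)
      dimnames(S) <- list(obj$bands, obj$bands)
      S
    })
    chols <- lapply(covs, chol)
    means <- lapply(obj$means, function(m) setNames(as.numeric(m), obj$bands))
    model <- list(classes = obj$classes, bands = obj$bands, means = means,
                  covariances = covs, chol = chols,
                  logdet = vapply(chols, function(ch) 2 * sum(log(diag(ch))),
                                  numeric(1)),
                  priors = setNames(as.numeric(obj$priors), obj$classes),
                  ridge = obj$ridge)
    class(model) <- "mlc_model"
  } else if (obj$type == "maxent_model") {
    W <- as.matrix(obj$weights)
    dimnames(W) <- list(obj$classes, c("(Intercept)", obj$bands))
    model <- list(classes = obj$classes, bands = obj$bands, weights = W,
                  center = setNames(as.numeric(obj$center), obj$bands),
                  scale = setNames(as.numeric(obj$scale), obj$bands),
                  lambda = obj$lambda, converged = obj$converged,
                  iterations = obj$iterations)
    class(model) <- "maxent_model"
  } else if (obj$type == "forest_model") {
    trees <- lapply(obj$trees, function(tr) {
      nodes <- matrix(as.integer(as.matrix(tr$nodes)), ncol = 4)
      list(nodes = nodes, thr = as.numeric(tr$thr))
    })
    model <- list(classes = obj$classes, bands = obj$bands, trees = trees,
                  n_trees = obj$n_trees, mtry = obj$mtry,
                  min_node = obj$min_node, seed = obj$seed)
    class(model) <- "forest_model"
  } else {
    stop("unknown model type in ", path)
  }
  model
}
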
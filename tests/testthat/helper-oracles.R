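# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# recursive flood fill over a binary matrix; returns component id per cell
flood_fill_components <- function(mask, connectivity = 4L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbrs4 <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nbrs8 <- rbind(nbrs4, cbind(c(-1, -1, 1, 1), c(-1, 1, -1, 1)))
  nbrs <- if (connectivity == 8L) nbrs8 else nbrs4
  comp <- 0L
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (mask[r0, c0] != 1L || lab[r0, c0] != 0L) next
      comp <- comp + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- comp
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nbrs))) {
          r <- cur[1] + nbrs[k, 1]; c <- cur[2] + nbrs[k, 2]
          if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
              mask[r, c] == 1L && lab[r, c] == 0L) {
            lab[r, c] <- comp
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# per-pixel Bayes-discriminant evaluation with plain loops and solve()
brute_force_mlc <- function(means, covs, priors, X) {
  K <- length(means)
  n <- nrow(X)
  G <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    Sinv <- solve(covs[[k]])
    ld <- determinant(covs[[k]], logarithm = TRUE)$modulus
    for (i in seq_len(n)) {
      d <- X[i, ] - means[[k]]
      G[i, k] <- log(priors[k]) - 0.5 * ld - 0.5 * drop(t(d) %*% Sinv %*% d)
    }
  }
  post <- t(apply(G, 1, function(g) {
    e <- exp(g - max(g)); e / sum(e)
  }))
  labels <- apply(G, 1, which.max)
  list(labels = labels, posterior = post, discriminants = G)
}

# classic even-odd ray casting (horizontal ray to +infinity)
point_in_poly_raycast <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

# tally a confusion matrix with a double loop
brute_force_tally <- function(truth, pred, classes) {
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(classes, classes))
  for (i in seq_along(truth)) {
    cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  }
  cm
}

# quick toy training set: K well-separated Gaussian blobs in `p` dims,
# several polygons per class so polygon-level splitting works
make_toy_training <- function(n_per_class = 60, p = 2, K = 3, sep = 8,
                              n_polys = 3, seed = 42,
                              classes = land_cover_classes()[seq_len(K)]) {
  set.seed(seed)
  X <- NULL; cls <- NULL; pid <- NULL
  for (k in seq_len(K)) {
    Xi <- matrix(rnorm(n_per_class * p), n_per_class, p) + (k - 1) * sep
    X <- rbind(X, Xi)
    cls <- c(cls, rep(classes[k], n_per_class))
    pid <- c(pid, rep((k - 1) * n_polys + seq_len(n_polys),
                      length.out = n_per_class))
  }
  colnames(X) <- paste0("b", seq_len(p))
  training_set(X, cls, pid, classes = classes)
}

# scenes shared by several test files (generated once per run)
small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_scene(scene_config(nrow = 60, ncol = 60, seed = 418))
    }
    cache
  }
})

# a default-configuration scene, big enough for the survey-style plan's
# per-class area targets to quantize cleanly
default_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_scene(scene_config(seed = 418))
    }
    cache
  }
})
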
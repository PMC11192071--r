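test_that("polygon-level split hits the 80/20 target and is seeded", {
  ts <- make_toy_training(n_per_class = 50, K = 2, n_polys = 10)
  sp <- split_train_val(ts, 0.8, seed = 5)
  for (cl in levels(droplevels(ts$class))) {
    expect_identical(length(unique(sp$train$polygon_id[sp$train$class == cl])), 8L)
    expect_identical(length(unique(sp$val$polygon_id[sp$val$class == cl])), 2L)
  }
  sp2 <- split_train_val(ts, 0.8, seed = 5)
  expect_identical(sp$train$polygon_id, sp2$train$polygon_id)
  # disjoint and covering
  expect_identical(length(sp$train) + length(sp$val), length(ts))
  expect_length(intersect(unique(sp$train$polygon_id),
                          unique(sp$val$polygon_id)), 0L)
  expect_error(split_train_val(make_toy_training(n_polys = 1), 0.8),
               "fewer than 2 polygons")
})

test_that("survey-plan splits keep every class on the validation side", {
  sc <- small_scene()
  plan <- survey_training_plan(sc$truth)
  polys <- generate_training_polygons(sc$truth, plan, seed = 9)
  ts <- extract_training_pixels(sc$swir, polys)
  sp <- split_train_val(ts, 0.8, seed = 1)
  expect_setequal(unique(as.character(sp$val$class)), land_cover_classes())
})

test_that("two equal-variance 1-D classes split at the midpoint", {
  X <- matrix(c(-1, 0, 1, 9, 10, 11), ncol = 1,
              dimnames = list(NULL, "b1"))
  ts <- training_set(X, rep(c("bare_soil", "mulch"), each = 3),
                     c(1, 1, 2, 3, 3, 4))
  m <- fit_mlc(ts)
  p <- classify_matrix_mlc(m, matrix(c(4.99, 5.01), ncol = 1))
  expect_identical(p$class, c("bare_soil", "mulch"))
  # pixel at a class mean goes to that class
  pm <- classify_matrix_mlc(m, matrix(c(0, 10), ncol = 1))
  expect_identical(pm$class, c("bare_soil", "mulch"))
})

test_that("MLC matches a brute-force Bayes-discriminant oracle", {
  set.seed(31)
  ts <- make_toy_training(n_per_class = 40, p = 3, K = 3, sep = 4)
  model <- fit_mlc(ts)
  vals <- array(runif(10 * 10 * 3) * 12, c(10, 10, 3))
  r <- multiband_raster(vals, paste0("b", 1:3), pixel_size = 3.7)
  pred <- predict_mlc(model, r)
  oracle <- brute_force_mlc(model$means, model$covariances, model$priors,
                            raster_to_matrix(r))
  got_labels <- as.vector(t(pred$labels))
  expect_identical(got_labels, as.integer(oracle$labels))
  for (k in seq_along(model$classes)) {
    got <- as.vector(t(pred$posterior[, , k]))
    expect_lt(max(abs(got - oracle$posterior[, k])), 1e-10)
  }
  # posteriors sum to one per pixel
  sums <- apply(pred$posterior, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
})

test_that("MLC recovers the generating class means within 3 standard errors", {
  sc <- generate_scene(scene_config(seed = 2024))
  lib <- default_spectral_library()
  spectra <- NULL; cls <- NULL; pid <- NULL
  for (cl in land_cover_classes()) {
    cells <- which(sc$truth$labels == match(cl, sc$truth$classes))
    expect_gt(length(cells), 500)
    cells <- cells[seq_len(500)]
    m <- sapply(1:8, function(b) sc$swir$values[, , b][cells])
    spectra <- rbind(spectra, m)
    cls <- c(cls, rep(cl, 500))
    pid <- c(pid, rep(match(cl, land_cover_classes()) * 2, 500))
  }
  colnames(spectra) <- band_names("swir")
  model <- fit_mlc(training_set(spectra, cls, pid))
  for (cl in land_cover_classes()) {
    se <- sqrt(diag(lib$covariances[[cl]])[9:16] / 500)
    delta <- abs(model$means[[cl]] - lib$means[cl, 9:16])
    expect_true(all(delta < 3 * se + 1e-9))
  }
})

test_that("nodata pixels stay unclassified", {
  ts <- make_toy_training(p = 2)
  model <- fit_mlc(ts)
  vals <- array(runif(18) * 10, c(3, 3, 2))
  vals[2, 2, ] <- NA
  r <- multiband_raster(vals, c("b1", "b2"), pixel_size = 1)
  pred <- predict_mlc(model, r)
  expect_true(is.na(pred$labels[2, 2]))
  expect_identical(sum(is.na(pred$labels)), 1L)
})

test_that("a single-class fit labels everything as that class", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("b1", "b2")))
  ts <- training_set(X, rep("grass", 20), rep(c(1, 2), 10))
  model <- suppressWarnings(fit_mlc(ts))
  p <- classify_matrix_mlc(model, matrix(rnorm(10), 5, 2))
  expect_true(all(p$class == "grass"))
})

test_that("maxent separates a separable toy and matches its gradient", {
  X <- matrix(c(rnorm(30, -1, 0.1), rnorm(30, 1, 0.1)), ncol = 1,
              dimnames = list(NULL, "b1"))
  ts <- training_set(X, rep(c("grass", "mulch"), each = 30),
                     rep(c(1, 2, 3, 4), each = 15))
  model <- fit_maxent(ts)
  expect_true(model$converged)
  p <- classify_matrix_maxent(model, X)
  expect_identical(p$class, as.character(ts$class))
  expect_lt(max(abs(rowSums(p$prob) - 1)), 1e-9)

  # finite-difference check of the penalized objective's gradient at the
  # fitted optimum: every directional derivative must vanish
  f0 <- maxent_objective(model, ts)
  h <- 1e-5
  num_grad <- model$weights
  for (i in seq_len(nrow(model$weights))) {
    for (j in seq_len(ncol(model$weights))) {
      Wp <- model$weights; Wp[i, j] <- Wp[i, j] + h
      Wm <- model$weights; Wm[i, j] <- Wm[i, j] - h
      num_grad[i, j] <- (maxent_objective(model, ts, Wp) -
                           maxent_objective(model, ts, Wm)) / (2 * h)
    }
  }
  expect_lt(max(abs(num_grad)), 1e-5)
  expect_lt(f0, maxent_objective(model, ts, model$weights + 0.01))
})

test_that("an overwhelming penalty drives maxent to uniform probabilities", {
  ts <- make_toy_training(K = 3)
  model <- fit_maxent(ts, lambda = 1e6)
  expect_lt(max(abs(model$weights)), 1e-4)
  p <- classify_matrix_maxent(model, ts$spectra[1:5, ])
  expect_lt(max(abs(p$prob - 1 / 3)), 1e-3)
})

test_that("maxent agrees with an independent multinomial fit", {
  skip_if_not_installed("nnet")
  ts <- make_toy_training(n_per_class = 80, p = 2, K = 3, sep = 5, seed = 8)
  model <- fit_maxent(ts)
  df <- data.frame(y = droplevels(ts$class), ts$spectra)
  ref <- nnet::multinom(y ~ b1 + b2, df, trace = FALSE)
  ours <- classify_matrix_maxent(model, ts$spectra)$class
  theirs <- as.character(predict(ref, df))
  expect_gt(mean(ours == theirs), 0.98)
})

test_that("forests are deterministic under a seed and learn a separable toy", {
  ts <- make_toy_training(n_per_class = 30, p = 2, K = 2, sep = 10)
  one <- fit_rf(ts, n_trees = 1, mtry = 2, seed = 4)
  p1 <- classify_matrix_rf(one, ts$spectra)
  expect_identical(p1$class, as.character(ts$class))

  a <- fit_rf(ts, n_trees = 25, seed = 11)
  b <- fit_rf(ts, n_trees = 25, seed = 11)
  pa <- classify_matrix_rf(a, ts$spectra)
  pb <- classify_matrix_rf(b, ts$spectra)
  expect_identical(pa$prob, pb$prob)
  c_ <- fit_rf(ts, n_trees = 25, seed = 12)
  expect_false(identical(c_$trees, a$trees))
})

test_that("the forest is competitive with an independent implementation", {
  skip_if_not_installed("randomForest")
  ts <- make_toy_training(n_per_class = 100, p = 4, K = 3, sep = 2, seed = 19)
  holdout <- make_toy_training(n_per_class = 100, p = 4, K = 3, sep = 2,
                               seed = 20)
  ours <- fit_rf(ts, n_trees = 200, seed = 3)
  acc_ours <- mean(classify_matrix_rf(ours, holdout$spectra)$class ==
                     as.character(holdout$class))
  set.seed(3)
  ref <- randomForest::randomForest(ts$spectra, droplevels(ts$class),
                                    ntree = 200)
  acc_ref <- mean(as.character(predict(ref, holdout$spectra)) ==
                    as.character(holdout$class))
  expect_gt(acc_ours, acc_ref - 0.05)
})

test_that("models survive a JSON save/load round trip", {
  ts <- make_toy_training(K = 3)
  Xnew <- ts$spectra[seq(1, nrow(ts$spectra), by = 7), ]
  for (fit in list(fit_mlc(ts), fit_maxent(ts), fit_rf(ts, n_trees = 10))) {
    path <- tempfile(fileext = ".json")
    save_model(fit, path)
    back <- load_model(path)
    pred_fun <- switch(class(fit)[1],
      mlc_model = classify_matrix_mlc,
      maxent_model = classify_matrix_maxent,
      forest_model = classify_matrix_rf
    )
    expect_identical(pred_fun(back, Xnew)$label, pred_fun(fit, Xnew)$label)
    expect_equal(pred_fun(back, Xnew)$prob, pred_fun(fit, Xnew)$prob,
                 tolerance = 1e-12)
  }
})

test_that("stacked rasters classify identically to pre-joined spectra", {
  sc <- small_scene()
  up <- resample(sc$swir, sc$vnir$pixel_size)
  st <- stack_bands(sc$vnir, up)
  plan <- survey_training_plan(sc$truth)
  polys <- generate_training_polygons(sc$truth, plan, seed = 2)
  ts_stack <- extract_training_pixels(st, polys)
  ts_v <- extract_training_pixels(sc$vnir, polys)
  ts_s <- extract_training_pixels(up, polys)
  joined <- cbind(ts_v$spectra, ts_s$spectra)
  colnames(joined) <- st$band_names
  expect_identical(ts_stack$spectra, joined)
  m_stack <- fit_mlc(ts_stack)
  m_join <- fit_mlc(training_set(joined, ts_v$class, ts_v$polygon_id))
  X <- raster_to_matrix(st)[seq(1, 1000, 13), ]
  expect_identical(classify_matrix_mlc(m_stack, X)$label,
                   classify_matrix_mlc(m_join, X)$label)
})
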
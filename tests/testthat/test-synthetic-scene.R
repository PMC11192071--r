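test_that("default spectral library has six classes, sixteen SPD covariances", {
  lib <- default_spectral_library()
  expect_setequal(lib$classes, land_cover_classes())
  expect_length(lib$classes, 6L)
  expect_length(lib$bands, 16L)
  expect_identical(lib$bands, band_names("all"))
  expect_true(all(lib$means >= 0 & lib$means <= 255))
  for (cl in lib$classes) {
    S <- lib$covariances[[cl]]
    expect_true(isSymmetric(S))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("mulch separates in SWIR but overlaps bedrock in VNIR", {
  lib <- default_spectral_library()
  swir <- band_names("swir")
  vnir <- band_names("vnir")
  for (other in setdiff(lib$classes, "mulch")) {
    expect_gte(mahalanobis_separation(lib, "mulch", other, swir), 3.0)
  }
  expect_lte(mahalanobis_separation(lib, "mulch", "bedrock_colluvium", vnir),
             1.0)
})

test_that("scene geometry follows the two sensor resolutions", {
  sc <- generate_scene(scene_config(nrow = 200, ncol = 200, seed = 3,
                                    fractions = c(mulch = 0.05)))
  expect_identical(dim(sc$swir), c(200L, 200L, 8L))
  # 200 * 3.7 / 1.2 = 616.67 -> 617
  expect_identical(dim(sc$vnir), c(617L, 617L, 8L))
  expect_identical(dim(sc$truth), c(200L, 200L))
  expect_identical(sc$swir$band_names, band_names("swir"))
  expect_identical(sc$vnir$band_names, band_names("vnir"))
  # same extent on both grids up to sub-pixel rounding
  expect_lt(max(abs(raster_extent(sc$swir) - raster_extent(sc$vnir))), 1.2)
})

test_that("identical config and seed reproduce bit-identical scenes", {
  cfg <- scene_config(nrow = 50, ncol = 50, seed = 77)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$swir$values, b$swir$values)
  expect_identical(a$vnir$values, b$vnir$values)
  expect_identical(a$truth$labels, b$truth$labels)
})

test_that("invalid configs are rejected", {
  expect_error(scene_config(nrow = 0), "positive")
  expect_error(scene_config(fractions = c(mulch = 0.7, grass = 0.6)),
               "sum")
  expect_error(scene_config(fractions = c(lava = 0.1)), "unknown class")
})

test_that("realized mulch cover tracks the configured fraction", {
  shares <- vapply(1:10, function(s) {
    sc <- generate_scene(scene_config(seed = s))
    mean(sc$truth$labels == match("mulch", sc$truth$classes))
  }, numeric(1))
  expect_true(all(abs(shares - 0.05) <= 0.02))
})

test_that("generated spectra match the library class models", {
  sc <- small_scene()
  lib <- default_spectral_library()
  k <- match("mulch", sc$truth$classes)
  cells <- which(sc$truth$labels == k)
  n <- length(cells)
  expect_gt(n, 100)
  for (b in 1:8) {
    mu_hat <- mean(sc$swir$values[, , b][cells])
    mu <- lib$means["mulch", 8 + b]
    se <- sqrt(lib$covariances[["mulch"]][8 + b, 8 + b] / n)
    expect_lt(abs(mu_hat - mu), 3 * se + 1e-9)
  }
})

test_that("training polygons honor the survey plan", {
  sc <- default_scene()
  plan <- survey_training_plan(sc$truth)
  expect_identical(sum(plan$n_features), 224L)
  polys <- generate_training_polygons(sc$truth, plan, seed = 9)
  expect_length(polys, 224L)
  counts <- table(factor(polys$class, levels = plan$class))
  expect_identical(as.integer(counts), plan$n_features)
  # per-class realized area within +-25% of the plan targets
  areas <- tapply(polygon_areas(polys), factor(polys$class, plan$class), sum)
  expect_true(all(abs(areas / plan$target_area_m2 - 1) <= 0.25))
})

test_that("every training polygon lies wholly inside its class region", {
  sc <- small_scene()
  plan <- survey_training_plan(sc$truth)
  polys <- generate_training_polygons(sc$truth, plan, seed = 9)
  lab <- rasterize_polygons(polys, sc$truth)
  covered <- !is.na(lab$labels)
  expect_true(all(lab$labels[covered] == sc$truth$labels[covered]))
})

test_that("a one-class one-feature plan yields one contained polygon", {
  sc <- small_scene()
  plan <- training_plan("grass", 1L, 20 * 3.7^2)
  polys <- generate_training_polygons(sc$truth, plan, seed = 4)
  expect_length(polys, 1L)
  lab <- rasterize_polygons(polys, sc$truth)
  k <- match("grass", sc$truth$classes)
  inside <- which(!is.na(lab$labels))
  expect_gt(length(inside), 0)
  expect_true(all(sc$truth$labels[inside] == k))
})

test_that("plans for absent classes fail loudly", {
  sc <- small_scene()
  truth <- sc$truth
  truth$labels[truth$labels == match("urban_developed", truth$classes)] <-
    match("grass", truth$classes)
  plan <- training_plan("urban_developed", 2L, 100)
  expect_error(generate_training_polygons(truth, plan, seed = 1),
               "absent")
})
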
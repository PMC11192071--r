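test_that("raster write/read round-trips values and georeferencing", {
  v <- array(as.numeric(sample(0:255, 2 * 2 * 3, replace = TRUE)), c(2, 2, 3))
  r <- multiband_raster(v, c("a", "b", "c"), pixel_size = 3.7,
                        origin = c(660123, 7001234))
  path <- tempfile(fileext = ".tif")
  write_raster(r, path)
  r2 <- read_raster(path)
  # integer-valued digital numbers survive bit-exactly
  expect_identical(r2$values, r$values)
  expect_identical(r2$band_names, r$band_names)
  expect_identical(r2$pixel_size, r$pixel_size)
  expect_identical(r2$origin, r$origin)
  expect_identical(r2$crs, r$crs)
  # arbitrary doubles survive at 32-bit float precision
  rf <- multiband_raster(array(runif(12) * 255, c(2, 2, 3)),
                         c("a", "b", "c"), pixel_size = 1.2)
  write_raster(rf, path)
  expect_lt(max(abs(read_raster(path)$values - rf$values)), 1e-4)
})

test_that("16-band rasters keep all band names through disk", {
  sc <- small_scene()
  st <- stack_bands(select_bands(sc$swir, 1:8), sc$swir)
  st$band_names <- band_names("all")
  path <- tempfile(fileext = ".tif")
  write_raster(st, path)
  expect_length(read_raster(path)$band_names, 16L)
})

test_that("nodata cells survive the disk round trip and are never sampled", {
  v <- array(as.numeric(sample(1:255, 16, replace = TRUE)), c(4, 4, 1))
  v[1, 1, 1] <- NA; v[2, 3, 1] <- NA
  r <- multiband_raster(v, "b", pixel_size = 10, origin = c(0, 40))
  path <- tempfile(fileext = ".tif")
  write_raster(r, path)
  r2 <- read_raster(path)
  expect_identical(is.na(r2$values), is.na(r$values))
  expect_identical(r2$values, r$values)
  # a polygon over the whole raster yields only the 14 valid samples
  ring <- cbind(c(0, 40, 40, 0), c(40, 40, 0, 0))
  ps <- polygon_set(list(ring), class = "grass")
  ts <- extract_training_pixels(r2, ps)
  expect_identical(length(ts), 14L)
})

test_that("rasterization labels cells by centre containment", {
  template <- multiband_raster(matrix(0, 4, 4), "b", pixel_size = 3.7,
                               origin = c(0, 4 * 3.7))
  # polygon covering exactly the 4 cell centres of rows 1:2, cols 1:2
  ring <- cbind(c(0, 2 * 3.7, 2 * 3.7, 0), c(4 * 3.7, 4 * 3.7, 2 * 3.7, 2 * 3.7))
  lab <- rasterize_polygons(polygon_set(list(ring), "mulch"), template)
  expect_identical(sum(!is.na(lab$labels)), 4L)
  expect_true(all(which(!is.na(lab$labels)) %in% c(1, 2, 5, 6)))
})

test_that("overlapping polygons resolve to the first-listed class", {
  template <- multiband_raster(matrix(0, 4, 4), "b", pixel_size = 1,
                               origin = c(0, 4))
  full <- cbind(c(0, 4, 4, 0), c(4, 4, 0, 0))
  ps <- polygon_set(list(full, full), class = c("grass", "mulch"))
  lab <- rasterize_polygons(ps, template)
  expect_true(all(lab$labels == match("grass", lab$classes)))
})

test_that("polygons missing every cell centre label nothing", {
  template <- multiband_raster(matrix(0, 3, 3), "b", pixel_size = 3.7,
                               origin = c(0, 3 * 3.7))
  # a sliver in the cell corner, away from the centre
  ring <- cbind(c(0, 1, 1, 0), c(1, 1, 0, 0))
  lab <- rasterize_polygons(polygon_set(list(ring), "mulch"), template)
  expect_identical(sum(!is.na(lab$labels)), 0L)
})

test_that("extraction tags samples with class and polygon id", {
  v <- array(runif(16) * 100, c(4, 4, 2))
  r <- multiband_raster(v, c("x", "y"), pixel_size = 1, origin = c(0, 4))
  ring <- cbind(c(0, 2, 2, 0), c(4, 4, 2, 2))
  ps <- polygon_set(list(ring), class = "forest_trees", id = 7L)
  ts <- extract_training_pixels(r, ps)
  expect_identical(length(ts), 4L)
  expect_true(all(ts$class == "forest_trees"))
  expect_true(all(ts$polygon_id == 7L))
  # row-major deterministic order
  expect_identical(ts$spectra[, 1],
                   c(v[1, 1, 1], v[1, 2, 1], v[2, 1, 1], v[2, 2, 1]))
})

test_that("per-class sample counts are proportional to planned areas", {
  sc <- default_scene()
  plan <- survey_training_plan(sc$truth)
  polys <- generate_training_polygons(sc$truth, plan, seed = 9)
  ts <- extract_training_pixels(sc$swir, polys)
  counts <- table(ts$class)[plan$class]
  expected <- plan$target_area_m2 / sc$swir$pixel_size^2
  expect_true(all(abs(as.numeric(counts) / expected - 1) <= 0.25))
})

test_that("cubic resampling preserves constants and extents", {
  rc <- multiband_raster(matrix(77.5, 20, 20), "b", pixel_size = 3.7)
  out <- resample(rc, 1.2)
  expect_lt(max(abs(out$values - 77.5)), 1e-9)
  big <- multiband_raster(matrix(0, 200, 200), "b", pixel_size = 3.7)
  expect_identical(dim(resample(big, 1.2))[1:2], c(617L, 617L))
  expect_error(resample(rc, -1), "positive")
})

test_that("down-up resampling round trip stays within 2% of dynamic range", {
  # smooth synthetic surface
  g <- outer(seq(0, 2 * pi, length.out = 40), seq(0, 2 * pi, length.out = 40),
             function(a, b) 120 + 60 * sin(a) * cos(b))
  r <- multiband_raster(g, "b", pixel_size = 3.7)
  back <- resample(resample(r, 1.2), 3.7)
  mad <- mean(abs(back$values - r$values))
  expect_lt(mad / diff(range(g)), 0.02)
})

test_that("resampling propagates nodata", {
  m <- matrix(runif(100) * 100, 10, 10)
  m[5, 5] <- NA
  r <- multiband_raster(m, "b", pixel_size = 2)
  out <- resample(r, 1)
  expect_true(anyNA(out$values))
  # the four fine cells inside the nodata coarse cell must be nodata
  expect_true(all(is.na(out$values[9:10, 9:10, 1])))
})

test_that("polygon GeoJSON round trip preserves geometry, class, area", {
  rings <- list(cbind(c(0, 10, 10, 0), c(10, 10, 0, 0)),
                cbind(c(20, 26, 23), c(0, 0, 9)))
  ps <- polygon_set(rings, class = c("mulch", "grass"), id = c(3L, 8L))
  path <- tempfile(fileext = ".geojson")
  write_polygons(ps, path)
  ps2 <- read_polygons(path)
  expect_identical(length(ps2), 2L)
  expect_identical(ps2$class, ps$class)
  expect_identical(ps2$id, ps$id)
  expect_equal(polygon_areas(ps2), polygon_areas(ps))
  expect_equal(polygon_centroids(ps2), polygon_centroids(ps))
})
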
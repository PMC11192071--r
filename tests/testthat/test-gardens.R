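make_label <- function(m, pixel_size = 3.7, origin = NULL) {
  if (is.null(origin)) origin <- c(0, nrow(m) * pixel_size)
  label_raster(m, land_cover_classes(), pixel_size, origin)
}

test_that("a 2x2 mulch block becomes one polygon of 54.76 m2", {
  m <- matrix(match("grass", land_cover_classes()), 5, 5)
  m[2:3, 2:3] <- match("mulch", land_cover_classes())
  gs <- polygonize(make_label(m))
  expect_identical(nrow(gs), 1L)
  expect_equal(gs$area_m2, 4 * 3.7^2)
  expect_equal(gs$area_m2, 54.76)
})

test_that("diagonal neighbours split under 4-connectivity, merge under 8", {
  m <- matrix(match("grass", land_cover_classes()), 4, 4)
  mu <- match("mulch", land_cover_classes())
  m[1, 1] <- mu; m[2, 2] <- mu
  expect_identical(nrow(polygonize(make_label(m))), 2L)
  expect_identical(nrow(polygonize(make_label(m), connectivity = 8L)), 1L)
})

test_that("components match a flood-fill oracle on random grids", {
  set.seed(55)
  for (rep in 1:5) {
    m <- matrix(sample(c(4L, 5L), 400, replace = TRUE, prob = c(0.7, 0.3)),
                20, 20)
    gs <- polygonize(make_label(m))
    oracle <- flood_fill_components((m == 5L) * 1L)
    expect_identical(nrow(gs), max(oracle))
    expect_identical(sort(gs$n_cells), sort(unname(tabulate(oracle[oracle > 0]))))
    expect_equal(sum(gs$area_m2), sum(m == 5L) * 3.7^2)
  }
})

test_that("the minimum-mapping-unit filter removes strictly-smaller polygons", {
  # 1.2 m product: single cells are 1.44 m2, 3x3 blocks are 12.96 m2
  m <- matrix(4L, 12, 12)
  m[2, 2] <- 5L                 # 1.44 m2, dropped
  m[5:7, 5:7] <- 5L             # 12.96 m2, kept
  gs <- polygonize(make_label(m, pixel_size = 1.2))
  kept <- filter_min_area(gs, 10)
  expect_identical(nrow(gs), 2L)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$area_m2, 12.96)
  # boundary semantics: exactly min_area is kept
  gs2 <- polygonize(make_label(matrix(c(5L, 4L, 4L, 4L), 2, 2),
                               pixel_size = sqrt(10)))
  expect_identical(nrow(filter_min_area(gs2, 10)), 1L)
  # filtering is idempotent
  expect_identical(filter_min_area(kept, 10)$id, kept$id)
})

test_that("filtering matches a direct enumeration over random gardens", {
  set.seed(21)
  m <- matrix(sample(c(4L, 5L), 3600, replace = TRUE, prob = c(0.8, 0.2)),
              60, 60)
  gs <- polygonize(make_label(m, pixel_size = 1.2))
  kept <- filter_min_area(gs, 10)
  expect_identical(sort(kept$id), sort(gs$id[gs$area_m2 >= 10]))
})

test_that("exclusion masks drop exactly the centroid-contained gardens", {
  set.seed(3)
  m <- matrix(sample(c(4L, 5L), 900, replace = TRUE, prob = c(0.75, 0.25)),
              30, 30)
  lr <- make_label(m)
  gs <- polygonize(lr)
  ext <- raster_extent(lr)
  # half-plane mask: the western half of the map
  half <- polygon_set(list(cbind(
    c(ext["xmin"], (ext["xmin"] + ext["xmax"]) / 2,
      (ext["xmin"] + ext["xmax"]) / 2, ext["xmin"]),
    c(ext["ymax"], ext["ymax"], ext["ymin"], ext["ymin"])
  )))
  out <- apply_exclusion_mask(gs, half)
  manual <- vapply(seq_len(nrow(gs)), function(i) {
    point_in_poly_raycast(gs$centroid_x[i], gs$centroid_y[i],
                          half$rings[[1]])
  }, logical(1))
  # ray casting is boundary-ambiguous; compare away from the seam
  on_seam <- abs(gs$centroid_x - (ext[["xmin"]] + ext[["xmax"]]) / 2) < 1e-9
  expect_identical(sort(out$id[!on_seam[match(out$id, gs$id)]]),
                   sort(gs$id[!manual & !on_seam]))
  expect_identical(attr(out, "dropped")$n, as.integer(nrow(gs) - nrow(out)))

  # full-extent mask empties the set; empty mask is the identity
  full <- polygon_set(list(cbind(
    c(ext["xmin"] - 1, ext["xmax"] + 1, ext["xmax"] + 1, ext["xmin"] - 1),
    c(ext["ymax"] + 1, ext["ymax"] + 1, ext["ymin"] - 1, ext["ymin"] - 1)
  )))
  expect_identical(nrow(apply_exclusion_mask(gs, full)), 0L)
  empty <- polygon_set(list())
  expect_identical(nrow(apply_exclusion_mask(gs, empty)), nrow(gs))
})

test_that("total area sums and converts units", {
  m <- matrix(4L, 20, 20)
  m[1:10, 1:10] <- 5L
  gs <- polygonize(make_label(m))
  ta <- total_area(gs)
  expect_equal(ta$m2, 100 * 13.69)
  expect_equal(ta$ha, 0.1369)
  expect_equal(ta$km2, 0.001369)
  empty <- filter_min_area(gs, 1e9)
  expect_identical(total_area(empty)$m2, 0)
})

test_that("polygonized area equals mulch cell count times pixel area", {
  sc <- small_scene()
  gs <- polygonize(sc$truth)
  n_mulch <- sum(sc$truth$labels == match("mulch", sc$truth$classes))
  expect_equal(total_area(gs)$m2, n_mulch * sc$truth$pixel_size^2)
})

test_that("cellsum density conserves area and localizes single gardens", {
  m <- matrix(4L, 40, 40)
  m[5:6, 30:31] <- 5L
  gs <- polygonize(make_label(m))
  d <- kernel_density(gs, cell = 50)
  expect_identical(sum(d$grid > 0), 1L)
  expect_equal(sum(d$grid), total_area(gs)$m2)

  sc <- small_scene()
  gs2 <- polygonize(sc$truth)
  d2 <- kernel_density(gs2, cell = 100)
  expect_equal(sum(d2$grid), total_area(gs2)$m2)
  expect_error(kernel_density(gs2, cell = -5), "positive")
})

test_that("the quartic kernel vanishes beyond its bandwidth", {
  m <- matrix(4L, 40, 40)
  m[20, 20] <- 5L
  gs <- polygonize(make_label(m, pixel_size = 10, origin = c(0, 400)))
  d <- kernel_density(gs, cell = 20, bandwidth = 60, mode = "quartic")
  xc <- d$origin[1] + (seq_len(ncol(d$grid)) - 0.5) * d$cell
  yc <- d$origin[2] - (seq_len(nrow(d$grid)) - 0.5) * d$cell
  dist <- sqrt(outer((yc - gs$centroid_y)^2, (xc - gs$centroid_x)^2, `+`))
  expect_true(all(d$grid[dist >= 60] == 0))
  expect_true(all(d$grid[dist < 60] > 0))
})

test_that("coastal-biased mulch concentrates density in the eastern half", {
  east_heavier <- vapply(1:5, function(s) {
    sc <- generate_scene(scene_config(seed = s))
    gs <- polygonize(sc$truth)
    d <- kernel_density(gs, cell = 100)
    half <- ncol(d$grid) %/% 2
    sum(d$grid[, (half + 1):ncol(d$grid)]) > sum(d$grid[, 1:half])
  }, logical(1))
  expect_true(all(east_heavier))
})

test_that("garden polygons export to GeoJSON with conserved area", {
  m <- matrix(4L, 10, 10)
  m[2:3, 2:4] <- 5L
  gs <- polygonize(make_label(m))
  path <- tempfile(fileext = ".geojson")
  write_gardens_geojson(gs, path)
  back <- read_polygons(path)
  expect_identical(length(back), sum(vapply(attr(gs, "cells"), nrow,
                                            integer(1))))
  expect_equal(sum(polygon_areas(back)), total_area(gs)$m2)
})
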
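#' Scene configuration
#'
#' Parameters of the synthetic paired-sensor scene: grid size at SWIR
#' resolution, the two pixel sizes, target per-class cover fractions, patch
#' geometry, and the random seed. The VNIR grid dimensions are the SWIR
#' dimensions scaled by `swir_pixel_size / vnir_pixel_size`, rounded to
#' integers. Classes not named in `fractions` (here: grass) form the
#' background. Mulch patch centres are biased toward the high-x ("coastal")
#' edge of the map so that density surfaces have spatial structure.
#'
#' @param nrow,ncol SWIR grid dimensions (default 120 x 120).
#' @param swir_pixel_size,vnir_pixel_size Pixel sizes in metres (defaults
#'   3.7 and 1.2, the two sensor resolutions).
#' @param fractions Named target cover fractions for the non-background
#'   classes; must sum to <= 1.
#' @param patch_axes Named list of semi-axis ranges (in SWIR cells) for the
#'   elliptical patches of each class.
#' @param boundary_jitter Relative radial jitter applied to patch boundaries.
#' @param coastal_bias Strength in (0, 1] of the eastward bias of mulch
#'   patch centres (1 = uniform, smaller = more coastal).
#' @param seed Integer seed; scenes are pure functions of (config, library).
#' @param origin,crs Georeferencing of the top-left corner.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(nrow = 120, ncol = 120,
                         swir_pixel_size = 3.7, vnir_pixel_size = 1.2,
                         fractions = c(bare_soil = 0.10,
                                       bedrock_colluvium = 0.12,
                                       forest_trees = 0.15,
                                       mulch = 0.05,
                                       urban_developed = 0.04),
                         patch_axes = list(bare_soil = c(3, 7),
                                           bedrock_colluvium = c(3, 7),
                                           forest_trees = c(8, 14),
                                           mulch = c(3, 6),
                                           urban_developed = c(4, 7)),
                         boundary_jitter = 0.2,
                         coastal_bias = 0.35,
                         seed = 1L,
                         origin = c(660000, 7000000), crs = "EPSG:32712") {
  if (nrow <= 0 || ncol <= 0) stop("grid dimensions must be positive")
  if (swir_pixel_size <= 0 || vnir_pixel_size <= 0) {
    stop("pixel sizes must be positive")
  }
  if (any(fractions < 0) || sum(fractions) > 1) {
    stop("class fractions must be nonnegative and sum to at most 1")
  }
  bad <- setdiff(names(fractions), land_cover_classes())
  if (length(bad)) stop("unknown class in fractions: ", paste(bad, collapse = ", "))
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         swir_pixel_size = swir_pixel_size, vnir_pixel_size = vnir_pixel_size,
         fractions = fractions, patch_axes = patch_axes,
         boundary_jitter = boundary_jitter, coastal_bias = coastal_bias,
         seed = as.integer(seed), origin = origin, crs = crs),
    class = "scene_config"
  )
}

# place seeded elliptical patches of one class onto `truth` (modified in the
# caller), assigning only background cells, until `target` cells are reached
place_patches <- function(truth, class_idx, bg_idx, target, axes, jitter,
                          col_bias = NULL) {
  nr <- nrow(truth); nc <- ncol(truth)
  assigned <- 0L
  guard <- 0L
  while (assigned < target && guard < 10000L) {
    guard <- guard + 1L
    a <- runif(1, axes[1], axes[2])
    b <- runif(1, axes[1], axes[2])
    r0 <- runif(1, 1, nr)
    c0 <- if (is.null(col_bias)) {
      runif(1, 1, nc)
    } else {
      # beta-distributed toward the high-column ("coastal") edge
      nc * stats::rbeta(1, shape1 = 1 / col_bias, shape2 = 1)
    }
    rr <- max(1L, floor(r0 - a - 1)):min(nr, ceiling(r0 + a + 1))
    cc <- max(1L, floor(c0 - b - 1)):min(nc, ceiling(c0 + b + 1))
    dr <- (rr - r0) / a
    dc <- (cc - c0) / b
    r2 <- outer(dr^2, dc^2, `+`)
    inside <- r2 <= 1 + runif(length(r2), -jitter, jitter)
    sub <- truth[rr, cc, drop = FALSE]
    take <- inside & sub == bg_idx
    if (!any(take)) next
    sub[take] <- class_idx
    truth[rr, cc] <- sub
    assigned <- assigned + sum(take)
  }
  truth
}

# draw n spectra from the class Gaussian restricted to `band_idx`, clipped
# (not wrapped) into the 8-bit range [0, 255]
draw_class_spectra <- function(library, class_name, band_idx, n) {
  mu <- library$means[class_name, band_idx]
  S <- library$covariances[[class_name]][band_idx, band_idx]
  L <- chol(S)
  z <- matrix(rnorm(n * length(band_idx)), n, length(band_idx))
  x <- z %*% L + matrix(mu, n, length(band_idx), byrow = TRUE)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

# fill a multiband raster's values for the cells of each class
fill_scene_values <- function(labels, library, band_idx) {
  nr <- nrow(labels); nc <- ncol(labels)
  nb <- length(band_idx)
  vals <- array(NA_real_, c(nr, nc, nb))
  for (k in seq_along(library$classes)) {
    cells <- which(labels == k)
    if (!length(cells)) next
    x <- draw_class_spectra(library, library$classes[k], band_idx, length(cells))
    for (b in seq_len(nb)) {
      layer <- vals[, , b]
      layer[cells] <- x[, b]
      vals[, , b] <- layer
    }
  }
  vals
}

#' Generate a synthetic paired VNIR/SWIR scene
#'
#' Builds a ground-truth class map by placing seeded random elliptical
#' patches (with jittered boundaries) for each non-background class on a
#' grass background, then draws every pixel's reflectance from its class's
#' Gaussian spectral model: the 8 SWIR bands at SWIR resolution on the
#' coarse grid, and the 8 VNIR bands at VNIR resolution on the fine grid
#' (truth upsampled by nearest-neighbour). The same config (including its
#' seed) always reproduces bit-identical outputs.
#'
#' @param config A [scene_config()].
#' @param library A [spectral_library()] (default [default_spectral_library()]).
#' @return A list with elements `vnir` and `swir` ([multiband_raster()]s)
#'   and `truth` (a [label_raster()] on the SWIR grid).
#' @export
#' @examples
#' sc <- generate_scene(scene_config(nrow = 40, ncol = 40, seed = 7))
#' dim(sc$swir)
generate_scene <- function(config, library = default_spectral_library()) {
  stopifnot(inherits(config, "scene_config"))
  classes <- library$classes
  bg <- match("grass", classes)
  with_seed(config$seed, {
    nr <- config$nrow; nc <- config$ncol
    truth <- matrix(bg, nr, nc)
    for (cl in names(config$fractions)) {
      k <- match(cl, classes)
      target <- round(config$fractions[[cl]] * nr * nc)
      if (target <= 0) next
      truth <- place_patches(
        truth, k, bg, target, config$patch_axes[[cl]],
        config$boundary_jitter,
        col_bias = if (cl == "mulch") config$coastal_bias else NULL
      )
    }
    swir_vals <- fill_scene_values(truth, library, band_idx = 9:16)
    # VNIR grid: same extent, finer cells
    scale <- config$swir_pixel_size / config$vnir_pixel_size
    nrv <- as.integer(round(nr * scale))
    ncv <- as.integer(round(nc * scale))
    # map VNIR cell centres into SWIR cells (nearest / containing cell)
    rmap <- pmin(nr, pmax(1L, ceiling((seq_len(nrv) - 0.5) *
                                        config$vnir_pixel_size /
                                        config$swir_pixel_size)))
    cmap <- pmin(nc, pmax(1L, ceiling((seq_len(ncv) - 0.5) *
                                        config$vnir_pixel_size /
                                        config$swir_pixel_size)))
    truth_v <- truth[rmap, cmap, drop = FALSE]
    vnir_vals <- fill_scene_values(truth_v, library, band_idx = 1:8)
    list(
      vnir = multiband_raster(vnir_vals, band_names("vnir"),
                              config$vnir_pixel_size, config$origin,
                              config$crs),
      swir = multiband_raster(swir_vals, band_names("swir"),
                              config$swir_pixel_size, config$origin,
                              config$crs),
      truth = label_raster(truth, classes, config$swir_pixel_size,
                           config$origin, config$crs)
    )
  })
}
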
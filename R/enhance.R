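#' PCA component-substitution pan-sharpening
#'
#' Raises the 8-band SWIR raster to VNIR resolution: (1) cubic-resample
#' SWIR to the VNIR grid; (2) run a PCA across the 8 resampled SWIR bands;
#' (3) build a high-resolution intensity layer as the per-pixel mean of the
#' VNIR bands and match it to PC1 by an affine (mean/variance) histogram
#' match, sign-aligned with PC1; (4) substitute PC1 by the matched
#' intensity; (5) invert the PCA. If PC1 has zero variance (spatially
#' constant input) the substitution is skipped and the resampled raster
#' returned unchanged.
#'
#' @param swir A [multiband_raster()] at the coarse resolution.
#' @param vnir A [multiband_raster()] at the fine resolution, co-registered
#'   (same origin and extent) with `swir`.
#' @param histogram_match Apply the affine match (default `TRUE`).
#' @return A [multiband_raster()] with the SWIR bands at VNIR resolution.
#' @export
pansharpen_pca <- function(swir, vnir, histogram_match = TRUE) {
  stopifnot(inherits(swir, "multiband_raster"),
            inherits(vnir, "multiband_raster"))
  if (vnir$pixel_size >= swir$pixel_size) {
    stop("vnir raster must be finer than the swir raster")
  }
  ext_s <- raster_extent(swir); ext_v <- raster_extent(vnir)
  if (max(abs(ext_s - ext_v)) > swir$pixel_size) {
    stop("swir and vnir extents are not co-registered")
  }
  up <- resample(swir, vnir$pixel_size, method = "cubic")
  d <- dim(up)
  X <- raster_to_matrix(up)
  valid <- !is.na(X[, 1]) & !is.na(raster_to_matrix(vnir)[, 1])
  Xv <- X[valid, , drop = FALSE]
  mu <- colMeans(Xv)
  S <- cov(Xv)
  ev <- eigen(S, symmetric = TRUE)
  if (ev$values[1] <= 1e-12) {
    return(up) # zero-variance degenerate input: pass through
  }
  if (ev$values[length(ev$values)] < -1e-8) stop("rank-deficient PCA")
  V <- ev$vectors
  scores <- sweep(Xv, 2, mu) %*% V
  intensity <- rowMeans(raster_to_matrix(vnir)[valid, , drop = FALSE])
  pc1 <- scores[, 1]
  if (histogram_match) {
    s_i <- sd(intensity)
    if (s_i > 0) {
      sgn <- if (cor(intensity, pc1) < 0) -1 else 1
      intensity <- (intensity - mean(intensity)) / s_i * sd(pc1) * sgn +
        mean(pc1)
    } else {
      intensity <- rep(mean(pc1), length(pc1))
    }
  }
  scores[, 1] <- intensity
  Xs <- scores %*% t(V) + matrix(mu, nrow(scores), ncol(X), byrow = TRUE)
  out <- array(NA_real_, d)
  for (b in seq_len(d[3])) {
    layer <- rep(NA_real_, length(valid))
    layer[valid] <- Xs[, b]
    out[, , b] <- matrix_to_layer(layer, d[1], d[2])
  }
  multiband_raster(out, swir$band_names, vnir$pixel_size, vnir$origin,
                   vnir$crs)
}

#' Stack two co-gridded rasters band-wise
#'
#' @param a,b [multiband_raster()]s on identical grids; `a`'s bands come
#'   first (the pipeline convention is VNIR then SWIR).
#' @return A [multiband_raster()] with `bands(a) + bands(b)` bands.
#' @export
stack_bands <- function(a, b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2]) ||
      abs(a$pixel_size - b$pixel_size) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-6) {
    stop("rasters are not on identical grids")
  }
  vals <- array(NA_real_, c(dim(a)[1:2], n_bands(a) + n_bands(b)))
  vals[, , seq_len(n_bands(a))] <- a$values
  vals[, , n_bands(a) + seq_len(n_bands(b))] <- b$values
  # harmonize nodata across the two sources
  na_cells <- is.na(a$values[, , 1]) | is.na(b$values[, , 1])
  if (any(na_cells)) {
    for (k in seq_len(dim(vals)[3])) {
      layer <- vals[, , k]
      layer[na_cells] <- NA_real_
      vals[, , k] <- layer
    }
  }
  multiband_raster(vals, c(a$band_names, b$band_names), a$pixel_size,
                   a$origin, a$crs)
}
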
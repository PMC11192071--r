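# Keys cubic-convolution kernel (a = -0.5), the classic resampling kernel
keys_weight <- function(s, a = -0.5) {
  s <- abs(s)
  w <- numeric(length(s))
  i1 <- s <= 1
  w[i1] <- (a + 2) * s[i1]^3 - (a + 3) * s[i1]^2 + 1
  i2 <- s > 1 & s < 2
  w[i2] <- a * s[i2]^3 - 5 * a * s[i2]^2 + 8 * a * s[i2] - 4 * a
  w
}

# sparse (n_out x n_in) interpolation matrix along one axis; `u` are the
# fractional input-cell coordinates of the output cell centres
cubic_weight_matrix <- function(u, n_in) {
  base <- floor(u)
  ii <- jj <- vv <- vector("list", 4L)
  for (k in -1:2) {
    idx <- base + k
    w <- keys_weight(u - idx)
    idx <- pmin(n_in, pmax(1L, idx)) # clamp at edges (weights still sum to 1)
    ii[[k + 2L]] <- seq_along(u)
    jj[[k + 2L]] <- idx
    vv[[k + 2L]] <- w
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(length(u), n_in))
}

#' Resample a raster to a new pixel size
#'
#' Cubic-convolution interpolation (Keys kernel), applied separably per
#' band; the output grid covers the same extent with dimensions
#' `round(extent / target_pixel_size)`. Nodata is propagated: an output
#' cell is nodata if any input cell contributing weight to it is nodata.
#'
#' @param raster A [multiband_raster()].
#' @param target_pixel_size New cell size in metres.
#' @param method `"cubic"` (default) or `"nearest"`.
#' @return A [multiband_raster()] at the new resolution.
#' @export
#' @examples
#' r <- multiband_raster(matrix(1, 20, 20), "b", pixel_size = 3.7)
#' dim(resample(r, 1.2))
resample <- function(raster, target_pixel_size, method = c("cubic", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(raster, "multiband_raster"))
  if (target_pixel_size <= 0) stop("target_pixel_size must be positive")
  d <- dim(raster)
  ratio <- raster$pixel_size / target_pixel_size
  nr_out <- as.integer(round(d[1] * ratio))
  nc_out <- as.integer(round(d[2] * ratio))
  if (nr_out < 1 || nc_out < 1) stop("degenerate extent after resampling")
  # fractional input coordinates of output cell centres
  ur <- (seq_len(nr_out) - 0.5) / ratio + 0.5
  uc <- (seq_len(nc_out) - 0.5) / ratio + 0.5
  out <- array(NA_real_, c(nr_out, nc_out, d[3]))
  if (method == "nearest") {
    ri <- pmin(d[1], pmax(1L, round(ur)))
    ci <- pmin(d[2], pmax(1L, round(uc)))
    for (b in seq_len(d[3])) out[, , b] <- raster$values[ri, ci, b]
  } else {
    Wr <- cubic_weight_matrix(ur, d[1])
    Wc <- cubic_weight_matrix(uc, d[2])
    na_in <- is.na(raster$values[, , 1])
    any_na <- any(na_in)
    if (any_na) {
      # contamination mask: positive weight on any nodata input cell
      touch <- as.matrix(abs(Wr) %*% na_in %*% Matrix::t(abs(Wc))) > 1e-12
    }
    for (b in seq_len(d[3])) {
      layer <- raster$values[, , b]
      if (any_na) layer[na_in] <- mean(layer, na.rm = TRUE)
      res <- as.matrix(Wr %*% layer %*% Matrix::t(Wc))
      if (any_na) res[touch] <- NA_real_
      out[, , b] <- res
    }
  }
  multiband_raster(out, raster$band_names, target_pixel_size, raster$origin,
                   raster$crs)
}

#' Aggregate a raster to a coarser grid by block averaging
#'
#' Each coarse cell averages the fine cells whose centres fall inside it
#' (nodata cells excluded). Used to check spectral consistency of
#' pan-sharpened products against the native-resolution original.
#'
#' @param raster A [multiband_raster()].
#' @param target_pixel_size Coarse cell size in metres (> pixel size).
#' @return A [multiband_raster()] at the coarse resolution.
#' @export
aggregate_raster <- function(raster, target_pixel_size) {
  stopifnot(target_pixel_size > raster$pixel_size)
  d <- dim(raster)
  ratio <- raster$pixel_size / target_pixel_size
  nr_out <- max(1L, as.integer(round(d[1] * ratio)))
  nc_out <- max(1L, as.integer(round(d[2] * ratio)))
  rmap <- pmin(nr_out, pmax(1L, ceiling((seq_len(d[1]) - 0.5) * ratio)))
  cmap <- pmin(nc_out, pmax(1L, ceiling((seq_len(d[2]) - 0.5) * ratio)))
  out <- array(NA_real_, c(nr_out, nc_out, d[3]))
  fr <- factor(rmap, levels = seq_len(nr_out))
  fc <- factor(cmap, levels = seq_len(nc_out))
  for (b in seq_len(d[3])) {
    sums <- tapply(raster$values[, , b], list(fr[row(raster$values[, , b])],
                                              fc[col(raster$values[, , b])]),
                   mean, na.rm = TRUE)
    out[, , b] <- as.numeric(sums)
  }
  multiband_raster(out, raster$band_names, target_pixel_size, raster$origin,
                   raster$crs)
}
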
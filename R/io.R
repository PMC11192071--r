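#' Read and write multiband rasters
#'
#' Rasters are stored as multi-page 32-bit TIFF files (one page per band,
#' values scaled by 1/256 into the unit interval) together with a JSON
#' sidecar `<path>.json` carrying band names, pixel size, origin, CRS and a
#' nodata flag. Nodata cells are written losslessly as an extra mask page.
#' Integer-valued digital numbers in the 0-255 range round-trip bit-exactly
#' (the sidecar records integer-valuedness and reading restores it);
#' arbitrary doubles round-trip at the 32-bit quantization precision of the
#' TIFF container (~6e-8 absolute in digital-number units).
#'
#' @param path Path to the `.tif` file; the sidecar lives at `<path>.json`.
#' @return `read_raster()` returns a [multiband_raster()]; `write_raster()`
#'   returns `path` invisibly.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  side <- paste0(path, ".json")
  meta <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::fromJSON(side)
  } else {
    warning("no georeferencing sidecar for ", path,
            "; assuming 1 m pixels at origin (0,0), EPSG:32712")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  has_mask <- isTRUE(meta$has_mask)
  nb <- length(pages) - if (has_mask) 1L else 0L
  scale <- if (!is.null(meta$scale)) meta$scale else 256
  vals <- array(NA_real_, c(dim(pages[[1]]), nb))
  for (b in seq_len(nb)) vals[, , b] <- pages[[b]] * scale
  if (isTRUE(meta$integer_valued)) vals <- round(vals)
  if (has_mask) {
    na_cells <- pages[[nb + 1L]] > 0.5
    if (any(na_cells)) {
      for (b in seq_len(nb)) {
        layer <- vals[, , b]
        layer[na_cells] <- NA_real_
        vals[, , b] <- layer
      }
    }
  }
  multiband_raster(
    vals,
    band_names = if (!is.null(meta$band_names)) meta$band_names else NULL,
    pixel_size = if (!is.null(meta$pixel_size)) meta$pixel_size else 1,
    origin = if (!is.null(meta$origin)) meta$origin else c(0, 0),
    crs = if (!is.null(meta$crs)) meta$crs else "EPSG:32712"
  )
}

#' @param r A `multiband_raster`. Values must lie in [0, 256).
#' @rdname read_raster
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "multiband_raster"))
  v <- r$values
  rng <- range(v, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] >= 256)) {
    stop("raster values outside the storable range [0, 256)")
  }
  na_cells <- is.na(v[, , 1])
  pages <- lapply(seq_len(dim(v)[3]), function(b) {
    layer <- v[, , b] / 256
    layer[is.na(layer)] <- 0
    layer
  })
  has_mask <- any(na_cells)
  if (has_mask) pages <- c(pages, list(na_cells * 1.0))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    band_names = r$band_names, pixel_size = r$pixel_size,
    origin = r$origin, crs = r$crs, scale = 256, has_mask = has_mask,
    integer_valued = all(v == round(v), na.rm = TRUE)
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a label raster
#'
#' Byte-valued class indices with the same TIFF + JSON sidecar layout as
#' [write_raster()]; 0 encodes unlabeled cells.
#'
#' @param lr A `label_raster`.
#' @param path Path to the `.tif` file.
#' @export
write_label_raster <- function(lr, path) {
  lab <- lr$labels
  lab[is.na(lab)] <- 0L
  tiff::writeTIFF(lab / 255, path, bits.per.sample = 8L)
  meta <- list(classes = lr$classes, pixel_size = lr$pixel_size,
               origin = lr$origin, crs = lr$crs)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_raster
#' @export
read_label_raster <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  lab <- round(tiff::readTIFF(path) * 255)
  lab[lab == 0] <- NA
  label_raster(matrix(as.integer(lab), nrow(lab), ncol(lab)),
               classes = meta$classes, pixel_size = meta$pixel_size,
               origin = meta$origin, crs = meta$crs)
}

#' Export a training set as CSV
#'
#' One row per pixel sample: class, polygon id, then one column per band.
#'
#' @param ts A `training_set`.
#' @param path Output CSV path.
#' @export
write_training_csv <- function(ts, path) {
  df <- data.frame(class = as.character(ts$class), polygon_id = ts$polygon_id,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(ts$spectra, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
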
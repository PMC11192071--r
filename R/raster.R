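#' Multiband raster container
#'
#' A minimal in-memory georeferenced raster: a `row x col x band` array of
#' reflectance values (unitless digital numbers, 0-255 range by convention)
#' on a square-pixel grid in a projected CRS. Cell (1,1) is the top-left
#' (north-west) cell; the x coordinate grows with column, y shrinks with row.
#' `NA` marks nodata and must be consistent across bands.
#'
#' @param values Numeric array `nrow x ncol x nband` (a matrix is promoted to
#'   one band).
#' @param band_names Character vector, one name per band.
#' @param pixel_size Cell edge length in metres (> 0).
#' @param origin Numeric length-2: x of the left edge, y of the top edge, in
#'   projected metres.
#' @param crs CRS identifier; a projected, metre-unit system is assumed
#'   (default `"EPSG:32712"`, UTM zone 12S).
#' @return An object of class `multiband_raster`.
#' @export
multiband_raster <- function(values, band_names = NULL, pixel_size,
                             origin = c(0, 0), crs = "EPSG:32712") {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  nb <- dim(values)[3]
  if (is.null(band_names)) band_names <- paste0("band_", seq_len(nb))
  if (length(band_names) != nb) {
    stop("band_names length (", length(band_names),
         ") does not match band count (", nb, ")")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("pixel_size must be a single positive number")
  }
  # nodata must agree across bands
  if (nb > 1L) {
    na1 <- is.na(values[, , 1L])
    for (b in 2L:nb) {
      if (!identical(na1, is.na(values[, , b]))) {
        stop("nodata (NA) cells differ between bands")
      }
    }
  }
  structure(
    list(values = values, band_names = as.character(band_names),
         pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin), crs = crs),
    class = "multiband_raster"
  )
}

#' @export
print.multiband_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<multiband_raster> %d x %d cells, %d band(s) @ %.3g m [%s]\n",
              d[1], d[2], d[3], x$pixel_size, x$crs))
  cat("  bands:", paste(x$band_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.multiband_raster <- function(x) dim(x$values)

n_bands <- function(r) dim(r$values)[3]

#' Raster extent
#'
#' @param r A `multiband_raster` or `label_raster`.
#' @return Named numeric vector `xmin, xmax, ymin, ymax` in projected metres.
#' @export
raster_extent <- function(r) {
  d <- dim(r)[1:2]
  c(xmin = r$origin[1],
    xmax = r$origin[1] + d[2] * r$pixel_size,
    ymin = r$origin[2] - d[1] * r$pixel_size,
    ymax = r$origin[2])
}

# x coordinates of column centers / y coordinates of row centers
col_centers <- function(r) r$origin[1] + (seq_len(dim(r)[2]) - 0.5) * r$pixel_size
row_centers <- function(r) r$origin[2] - (seq_len(dim(r)[1]) - 0.5) * r$pixel_size

#' Label raster
#'
#' A single-layer raster of land-cover class identifiers sharing the grid
#' convention of [multiband_raster()]. Labels are stored as integer indices
#' into `classes`; `NA` means unlabeled/nodata.
#'
#' @param labels Integer matrix of class indices (or a character matrix of
#'   class names, converted against `classes`).
#' @param classes Character vector of valid class names.
#' @inheritParams multiband_raster
#' @return An object of class `label_raster`.
#' @export
label_raster <- function(labels, classes = land_cover_classes(), pixel_size,
                         origin = c(0, 0), crs = "EPSG:32712") {
  if (is.character(labels)) {
    m <- match(labels, classes)
    if (any(!is.na(labels) & is.na(m))) stop("unknown class label in matrix")
    labels <- matrix(m, nrow(labels), ncol(labels))
  }
  stopifnot(is.matrix(labels))
  bad <- !is.na(labels) & (labels < 1L | labels > length(classes))
  if (any(bad)) stop("label indices out of range of the class list")
  structure(
    list(labels = matrix(as.integer(labels), nrow(labels), ncol(labels)),
         classes = classes, pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin), crs = crs),
    class = "label_raster"
  )
}

#' @export
dim.label_raster <- function(x) dim(x$labels)

#' @export
print.label_raster <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_raster> %d x %d cells @ %.3g m, %d classes\n",
              d[1], d[2], x$pixel_size, length(x$classes)))
  tb <- table(factor(x$classes[x$labels], levels = x$classes))
  print(tb)
  invisible(x)
}

#' Select bands of a raster
#'
#' @param r A `multiband_raster`.
#' @param bands Band names or indices.
#' @return A `multiband_raster` with the selected bands, in the given order.
#' @export
select_bands <- function(r, bands) {
  idx <- if (is.character(bands)) match(bands, r$band_names) else as.integer(bands)
  if (anyNA(idx) || any(idx < 1L) || any(idx > n_bands(r))) {
    stop("unknown band selection")
  }
  multiband_raster(r$values[, , idx, drop = FALSE], r$band_names[idx],
                   r$pixel_size, r$origin, r$crs)
}

# flatten raster values to a pixel x band matrix (row-major pixel order)
raster_to_matrix <- function(r) {
  d <- dim(r$values)
  # array is column-major over (row, col); we index pixels row-major:
  # pixel p = (row - 1) * ncol + col
  m <- matrix(NA_real_, d[1] * d[2], d[3])
  for (b in seq_len(d[3])) m[, b] <- as.vector(t(r$values[, , b]))
  colnames(m) <- r$band_names
  m
}

# inverse of raster_to_matrix for a single layer
matrix_to_layer <- function(v, nrow, ncol) matrix(v, nrow, ncol, byrow = TRUE)
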
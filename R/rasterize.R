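#' Rasterize labeled polygons onto a raster grid
#'
#' A cell is labeled if and only if its centre lies inside (or on the
#' boundary of) a polygon; where polygons overlap, the polygon listed first
#' in the set wins. This centre-containment rule is the standard,
#' deterministic rasterization convention.
#'
#' @param polygons A [polygon_set()] with class labels.
#' @param template A [multiband_raster()] or [label_raster()] supplying grid
#'   geometry.
#' @param classes Class list of the output (default the canonical six).
#' @return A [label_raster()]; cells outside every polygon are `NA`.
#' @export
rasterize_polygons <- function(polygons, template,
                               classes = land_cover_classes()) {
  if (!length(polygons)) stop("empty polygon set")
  if (!identical(polygons$crs, template$crs)) {
    stop("polygons and template use different CRSs")
  }
  d <- dim(template)[1:2]
  xs <- col_centers(template)
  ys <- row_centers(template)
  lab <- matrix(NA_integer_, d[1], d[2])
  # bounding-box prefilter per polygon, first-listed polygon wins
  for (j in seq_along(polygons$rings)) {
    ring <- polygons$rings[[j]]
    k <- match(polygons$class[j], classes)
    if (is.na(k)) stop("polygon class not in class list: ", polygons$class[j])
    ci <- which(xs >= min(ring[, 1]) & xs <= max(ring[, 1]))
    ri <- which(ys >= min(ring[, 2]) & ys <= max(ring[, 2]))
    if (!length(ci) || !length(ri)) next
    grid <- expand.grid(r = ri, c = ci)
    inside <- points_in_ring(xs[grid$c], ys[grid$r], ring)
    hit <- grid[inside & is.na(lab[cbind(grid$r, grid$c)]), , drop = FALSE]
    if (nrow(hit)) lab[cbind(hit$r, hit$c)] <- k
  }
  label_raster(lab, classes, template$pixel_size, template$origin,
               template$crs)
}

#' Training set of labeled pixel spectra
#'
#' @param spectra Numeric pixel x band matrix.
#' @param class Factor (or character) of class labels, one per pixel.
#' @param polygon_id Integer id of the source polygon per pixel.
#' @param classes Class levels (default the canonical six).
#' @return An object of class `training_set`.
#' @export
training_set <- function(spectra, class, polygon_id,
                         classes = land_cover_classes()) {
  spectra <- as.matrix(spectra)
  class <- factor(as.character(class), levels = classes)
  stopifnot(nrow(spectra) == length(class),
            nrow(spectra) == length(polygon_id), !anyNA(class))
  structure(list(spectra = spectra, class = class,
                 polygon_id = as.integer(polygon_id)),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d samples x %d bands, %d polygons\n",
              nrow(x$spectra), ncol(x$spectra),
              length(unique(x$polygon_id))))
  print(table(x$class))
  invisible(x)
}

#' @export
length.training_set <- function(x) nrow(x$spectra)

# subset samples of a training set
subset_training <- function(ts, idx) {
  training_set(ts$spectra[idx, , drop = FALSE], ts$class[idx],
               ts$polygon_id[idx], classes = levels(ts$class))
}

#' Extract labeled pixel samples under training polygons
#'
#' One sample per non-nodata cell whose centre falls inside a polygon,
#' tagged with the source polygon's id and class. Samples are emitted in
#' deterministic row-major cell order within polygon order. Polygons that
#' cover no valid cell are skipped with a warning.
#'
#' @param raster A [multiband_raster()].
#' @param polygons A [polygon_set()] with class labels.
#' @return A [training_set()].
#' @export
extract_training_pixels <- function(raster, polygons) {
  if (!identical(polygons$crs, raster$crs)) {
    stop("polygons and raster use different CRSs")
  }
  xs <- col_centers(raster)
  ys <- row_centers(raster)
  spectra <- list(); cls <- list(); pid <- list()
  for (j in seq_along(polygons$rings)) {
    ring <- polygons$rings[[j]]
    ci <- which(xs >= min(ring[, 1]) & xs <= max(ring[, 1]))
    ri <- which(ys >= min(ring[, 2]) & ys <= max(ring[, 2]))
    cells <- NULL
    if (length(ci) && length(ri)) {
      grid <- expand.grid(c = ci, r = ri)   # row-major: r slow? we want row-major
      grid <- grid[order(grid$r, grid$c), , drop = FALSE]
      inside <- points_in_ring(xs[grid$c], ys[grid$r], ring)
      cells <- grid[inside, , drop = FALSE]
    }
    if (is.null(cells) || !nrow(cells)) {
      warning("polygon ", polygons$id[j], " covers no cell centre; skipped")
      next
    }
    m <- matrix(NA_real_, nrow(cells), n_bands(raster))
    for (b in seq_len(n_bands(raster))) {
      m[, b] <- raster$values[, , b][cbind(cells$r, cells$c)]
    }
    valid <- !is.na(m[, 1])
    if (!any(valid)) {
      warning("polygon ", polygons$id[j], " covers only nodata cells; skipped")
      next
    }
    spectra[[length(spectra) + 1L]] <- m[valid, , drop = FALSE]
    cls[[length(cls) + 1L]] <- rep(polygons$class[j], sum(valid))
    pid[[length(pid) + 1L]] <- rep(polygons$id[j], sum(valid))
  }
  if (!length(spectra)) stop("no polygon yielded any training pixel")
  sp <- do.call(rbind, spectra)
  colnames(sp) <- raster$band_names
  training_set(sp, unlist(cls), unlist(pid))
}
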
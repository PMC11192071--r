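#' Labeled polygon set
#'
#' Planar polygons in a projected CRS, each a single closed ring, optionally
#' carrying a land-cover class label. Used for training polygons, exclusion
#' masks and garden outlines.
#'
#' @param rings List of two-column numeric matrices (x, y vertices in metres;
#'   the ring need not repeat its first vertex).
#' @param class Character vector of class labels (recycled; `NA` = unlabeled).
#' @param id Integer polygon identifiers (default sequential).
#' @param crs CRS identifier.
#' @return An object of class `polygon_set`.
#' @export
polygon_set <- function(rings, class = NA_character_, id = seq_along(rings),
                        crs = "EPSG:32712") {
  stopifnot(is.list(rings))
  rings <- lapply(rings, function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == 2L, nrow(m) >= 3L)
    storage.mode(m) <- "double"
    unname(m)
  })
  n <- length(rings)
  structure(
    list(rings = rings,
         class = rep_len(as.character(class), n),
         id = as.integer(rep_len(id, n)),
         crs = crs),
    class = "polygon_set"
  )
}

#' @export
length.polygon_set <- function(x) length(x$rings)

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("<polygon_set> %d polygon(s) [%s]\n", length(x), x$crs))
  tb <- table(x$class, useNA = "ifany")
  if (length(tb)) print(tb)
  invisible(x)
}

#' Subset a polygon set
#' @param x A `polygon_set`.
#' @param i Index vector.
#' @param ... Unused.
#' @export
`[.polygon_set` <- function(x, i, ...) {
  polygon_set(x$rings[i], x$class[i], x$id[i], x$crs)
}

# shoelace area of one ring (absolute value, m^2)
ring_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  n <- nrow(m)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# area centroid of one ring
ring_centroid <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  n <- nrow(m)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

#' Planar polygon areas
#'
#' @param ps A `polygon_set`.
#' @return Numeric vector of areas in square metres (shoelace formula).
#' @export
polygon_areas <- function(ps) vapply(ps$rings, ring_area, numeric(1))

#' Polygon centroids
#'
#' @param ps A `polygon_set`.
#' @return Two-column matrix of centroid coordinates (metres).
#' @export
polygon_centroids <- function(ps) {
  t(vapply(ps$rings, ring_centroid, numeric(2)))
}

# which of the points (x, y) fall inside ring `m` (boundary counts as inside)
points_in_ring <- function(x, y, m) {
  res <- pracma::inpolygon(x, y, m[, 1], m[, 2], boundary = TRUE)
  as.logical(res)
}

# index of the first polygon containing each point (NA if none); polygons
# earlier in the set win ties, matching the rasterization overlap rule
first_containing_polygon <- function(ps, x, y) {
  hit <- rep(NA_integer_, length(x))
  for (j in seq_along(ps$rings)) {
    todo <- is.na(hit)
    if (!any(todo)) break
    inside <- points_in_ring(x[todo], y[todo], ps$rings[[j]])
    hit[which(todo)[inside]] <- j
  }
  hit
}

#' Read / write polygons as GeoJSON
#'
#' Polygons are stored as a GeoJSON `FeatureCollection` of single-ring
#' `Polygon` features with `class` and `id` properties.
#'
#' @param path File path.
#' @return `read_polygons()` returns a [polygon_set()]; `write_polygons()`
#'   returns `path` invisibly.
#' @export
read_polygons <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(g$features)) stop("not a GeoJSON FeatureCollection: ", path)
  rings <- list(); cls <- character(); ids <- integer()
  for (f in g$features) {
    geom <- f$geometry
    if (is.null(geom) || !geom$type %in% c("Polygon", "MultiPolygon")) next
    polys <- if (geom$type == "Polygon") list(geom$coordinates) else geom$coordinates
    for (p in polys) {
      ring <- do.call(rbind, lapply(p[[1]], function(pt) unlist(pt)[1:2]))
      # drop repeated closing vertex if present
      if (nrow(ring) > 3 && all(ring[1, ] == ring[nrow(ring), ])) {
        ring <- ring[-nrow(ring), , drop = FALSE]
      }
      rings[[length(rings) + 1L]] <- ring
      cls <- c(cls, if (!is.null(f$properties$class)) f$properties$class else NA_character_)
      ids <- c(ids, if (!is.null(f$properties$id)) as.integer(f$properties$id) else length(rings))
    }
  }
  crs <- "EPSG:32712"
  if (!is.null(g$crs$properties$name)) crs <- g$crs$properties$name
  polygon_set(rings, cls, ids, crs)
}

#' @param ps A `polygon_set`.
#' @rdname read_polygons
#' @export
write_polygons <- function(ps, path) {
  feats <- lapply(seq_along(ps$rings), function(j) {
    m <- ps$rings[[j]]
    ring <- rbind(m, m[1, ]) # close the ring
    coords <- lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
    list(
      type = "Feature",
      properties = list(class = ps$class[j], id = ps$id[j]),
      geometry = list(type = "Polygon", coordinates = list(coords))
    )
  })
  obj <- list(
    type = "FeatureCollection",
    crs = list(type = "name", properties = list(name = ps$crs)),
    features = feats
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
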
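#' Training plan
#'
#' A per-class specification of how many training polygons ("features") to
#' digitize and how much total area they should cover. The default plan
#' mirrors the feature counts of the island survey's training dataset
#' (27 / 66 / 25 / 36 / 40 / 30 features over the six classes, 224 in
#' total) with per-class areas kept in the survey's proportions
#' (0.101 / 0.090 / 0.235 / 0.090 / 0.031 / 0.053 km2) but rescaled to a
#' desk-scale scene.
#'
#' @param classes Class names.
#' @param n_features Integer feature counts per class.
#' @param target_area_m2 Target total polygon area per class, m2.
#' @return A `data.frame` with class `training_plan`.
#' @export
training_plan <- function(classes, n_features, target_area_m2) {
  stopifnot(length(classes) == length(n_features),
            length(classes) == length(target_area_m2),
            all(n_features >= 1), all(target_area_m2 > 0))
  structure(
    data.frame(class = classes, n_features = as.integer(n_features),
               target_area_m2 = as.numeric(target_area_m2),
               stringsAsFactors = FALSE),
    class = c("training_plan", "data.frame")
  )
}

# survey proportions: features and km2 per class
SURVEY_FEATURES <- c(bare_soil = 27L, bedrock_colluvium = 66L,
                     forest_trees = 25L, grass = 36L, mulch = 40L,
                     urban_developed = 30L)
SURVEY_AREAS_KM2 <- c(bare_soil = 0.101, bedrock_colluvium = 0.090,
                      forest_trees = 0.235, grass = 0.090, mulch = 0.031,
                      urban_developed = 0.053)

#' @param truth A `label_raster` giving the scene the plan must fit into
#'   (used only for its total area), or `NULL` with `total_area_m2` given.
#' @param fraction Fraction of the scene area the training polygons should
#'   cover in total (default 0.12).
#' @param total_area_m2 Total training area; overrides `truth`/`fraction`.
#' @rdname training_plan
#' @export
survey_training_plan <- function(truth = NULL, fraction = 0.12,
                                 total_area_m2 = NULL) {
  if (is.null(total_area_m2)) {
    stopifnot(!is.null(truth))
    total_area_m2 <- prod(dim(truth)) * truth$pixel_size^2 * fraction
  }
  share <- SURVEY_AREAS_KM2 / sum(SURVEY_AREAS_KM2)
  training_plan(names(SURVEY_FEATURES), unname(SURVEY_FEATURES),
                unname(share * total_area_m2))
}

# rectangle (in cells) with h*w as close as possible to `t`, preferring the
# squarer option on ties
rect_dims <- function(t) {
  best <- c(1L, max(1L, as.integer(round(t))))
  best_err <- abs(prod(best) - t)
  for (h in seq_len(max(1L, floor(sqrt(t)) + 1L))) {
    w <- max(1L, as.integer(round(t / h)))
    err <- abs(h * w - t)
    if (err < best_err - 1e-9 ||
        (abs(err - best_err) <= 1e-9 && abs(h - w) < abs(best[1] - best[2]))) {
      best <- c(h, w)
      best_err <- err
    }
  }
  best
}

#' Generate labeled training polygons inside single-class regions
#'
#' Places axis-aligned rectangular polygons wholly inside single-class
#' regions of the ground truth, without mutual overlap, matching the plan's
#' per-class feature counts exactly and its per-class total areas as closely
#' as cell quantization allows (within +-25%). Polygon edges are aligned to
#' cell edges of the truth grid, so a polygon covers exactly its cells under
#' the centre-containment rasterization rule.
#'
#' @param truth A [label_raster()].
#' @param plan A [training_plan()].
#' @param seed Integer seed.
#' @param max_tries Placement attempts per polygon before the rectangle is
#'   shrunk.
#' @return A [polygon_set()] with `class` labels and sequential ids.
#' @export
generate_training_polygons <- function(truth, plan, seed = 1L,
                                       max_tries = 200L) {
  stopifnot(inherits(truth, "label_raster"), inherits(plan, "training_plan"))
  px <- truth$pixel_size
  nr <- nrow(truth$labels); nc <- ncol(truth$labels)
  present <- unique(truth$labels[!is.na(truth$labels)])
  with_seed(seed, {
    rings <- list(); cls <- character()
    used <- matrix(FALSE, nr, nc)
    for (i in seq_len(nrow(plan))) {
      cl <- plan$class[i]
      k <- match(cl, truth$classes)
      if (is.na(k) || !(k %in% present)) {
        stop("class absent from truth: ", cl)
      }
      cells <- which(truth$labels == k, arr.ind = TRUE)
      t_cells <- plan$target_area_m2[i] / px^2 / plan$n_features[i]
      dims <- rect_dims(t_cells)
      for (f in seq_len(plan$n_features[i])) {
        h <- dims[1]; w <- dims[2]
        placed <- FALSE
        repeat {
          for (try in seq_len(max_tries)) {
            pick <- cells[sample.int(nrow(cells), 1L), ]
            r0 <- pick[1]; c0 <- pick[2]
            if (r0 + h - 1L > nr || c0 + w - 1L > nc) next
            block_lab <- truth$labels[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
            block_used <- used[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
            if (all(block_lab == k, na.rm = FALSE) && !anyNA(block_lab) &&
                !any(block_used)) {
              used[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- TRUE
              x0 <- truth$origin[1] + (c0 - 1L) * px
              x1 <- truth$origin[1] + (c0 + w - 1L) * px
              y0 <- truth$origin[2] - (r0 - 1L) * px
              y1 <- truth$origin[2] - (r0 + h - 1L) * px
              rings[[length(rings) + 1L]] <-
                cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
              cls <- c(cls, cl)
              placed <- TRUE
              break
            }
          }
          if (placed) break
          # shrink and retry; give up only at 1x1
          if (h >= w && h > 1L) h <- h - 1L
          else if (w > 1L) w <- w - 1L
          else stop("cannot place a training polygon for class ", cl,
                    ": targets unattainable on this grid")
        }
      }
    }
    polygon_set(rings, cls, crs = truth$crs)
  })
}
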
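#' Polygon-stratified train/validation split
#'
#' Splits a training set 80/20 (by default) into training and validation
#' parts. The unit of assignment is the source polygon, not the pixel:
#' whole polygons are assigned to one side, per class, targeting the
#' fraction by polygon count. This prevents spatially autocorrelated pixels
#' of one polygon from appearing on both sides. A pixel-level split is
#' available behind `unit = "pixel"` for fidelity experiments.
#'
#' @param ts A [training_set()].
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed; identical seeds give identical membership.
#' @param unit `"polygon"` (default) or `"pixel"`.
#' @return A list with `train` and `val` training sets, disjoint and jointly
#'   covering `ts`.
#' @export
split_train_val <- function(ts, train_fraction = 0.8, seed = 1L,
                            unit = c("polygon", "pixel")) {
  unit <- match.arg(unit)
  stopifnot(inherits(ts, "training_set"),
            train_fraction > 0, train_fraction < 1)
  with_seed(seed, {
    if (unit == "pixel") {
      n <- nrow(ts$spectra)
      n_train <- max(1L, min(n - 1L, round(train_fraction * n)))
      idx <- sample.int(n)
      take <- sort(idx[seq_len(n_train)])
      return(list(train = subset_training(ts, take),
                  val = subset_training(ts, setdiff(seq_len(n), take))))
    }
    present <- levels(droplevels(ts$class))
    train_idx <- logical(nrow(ts$spectra))
    for (cl in present) {
      sel <- ts$class == cl
      polys <- unique(ts$polygon_id[sel])
      if (length(polys) < 2L) {
        stop("class ", cl, " has fewer than 2 polygons; ",
             "a polygon-level split needs at least one per side")
      }
      polys <- polys[sample.int(length(polys))]
      n_train <- max(1L, min(length(polys) - 1L,
                             round(train_fraction * length(polys))))
      train_polys <- polys[seq_len(n_train)]
      train_idx[sel & ts$polygon_id %in% train_polys] <- TRUE
    }
    list(train = subset_training(ts, which(train_idx)),
         val = subset_training(ts, which(!train_idx)))
  })
}
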
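#' Published reference accuracy metrics
#'
#' The two published accuracy tables for island-wide rock-garden
#' classification on Rapa Nui: the earlier WorldView-2 maximum-likelihood
#' study (three class-probability variants) and the WorldView-3 VNIR/SWIR
#' comparison of the three classifiers implemented here. These rows serve
#' as internal-consistency fixtures: every printed F1 must equal the
#' harmonic mean of its printed recall and precision. They are reference
#' data, not outputs of this package.
#'
#' @return A data frame with columns `study`, `imagery`, `classifier`,
#'   `recall`, `precision`, `f1`, `overall_accuracy`, `kappa`.
#' @export
reference_accuracy_metrics <- function() {
  data.frame(
    study = c(rep("worldview2_mlc", 3), rep("worldview3", 7)),
    imagery = c("vnir_maximal", "vnir_medial", "vnir_minimal",
                "vnir", "vnir", "vnir", "swir", "swir", "swir",
                "vnir_swir"),
    classifier = c("mlc", "mlc", "mlc",
                   "rf", "maxent", "mlc", "rf", "maxent", "mlc", "maxent"),
    recall = c(0.337, 0.327, 0.319,
               0.716, 0.701, 0.592, 0.753, 0.834, 0.743, 0.779),
    precision = c(0.671, 0.687, 0.753,
                  0.740, 0.697, 0.619, 0.715, 0.827, 0.744, 0.799),
    f1 = c(0.449, 0.443, 0.448,
           0.728, 0.699, 0.605, 0.734, 0.830, 0.743, 0.789),
    overall_accuracy = c(0.588, 0.591, 0.609,
                         0.7091, 0.695, 0.584, 0.7485, 0.8244, 0.7765,
                         0.7817),
    kappa = c(0.17, 0.18, 0.22,
              0.6505, 0.6342, 0.5002, 0.6915, 0.7865, 0.7248, 0.7378),
    stringsAsFactors = FALSE
  )
}
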
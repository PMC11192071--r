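#' Confusion matrix
#'
#' Counts of (true class, predicted class) pairs over a fixed class order.
#' Unclassified predictions (`NA`) are tallied in a dedicated
#' `unclassified` column; whether they enter accuracy denominators is
#' decided at metric time.
#'
#' @param truth,predicted Vectors of class labels (character, factor, or
#'   integer indices into `classes`); equal length. `NA` in `predicted`
#'   means unclassified; `NA` in `truth` drops the sample.
#' @param classes Class order (default the canonical six).
#' @return An integer matrix of class `confusion_matrix` with one row per
#'   true class and one column per predicted class plus `unclassified`.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  as_lab <- function(v, classes) {
    if (is.numeric(v)) classes[as.integer(v)] else as.character(v)
  }
  if (is.null(classes)) {
    classes <- if (is.factor(truth)) levels(truth) else land_cover_classes()
  }
  stopifnot(length(truth) == length(predicted))
  tr <- as_lab(truth, classes)
  pr <- as_lab(predicted, classes)
  keep <- !is.na(tr)
  tr <- tr[keep]; pr <- pr[keep]
  if (any(!is.na(tr) & !tr %in% classes) ||
      any(!is.na(pr) & !pr %in% classes)) {
    stop("label outside the class list")
  }
  pr[is.na(pr)] <- "unclassified"
  cm <- table(factor(tr, levels = classes),
              factor(pr, levels = c(classes, "unclassified")))
  cm <- matrix(as.integer(cm), nrow(cm), ncol(cm),
               dimnames = dimnames(cm))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Accuracy metrics from a confusion matrix
#'
#' Computes every metric the accuracy assessment reports: per-class recall
#' (= true-positive rate), precision, F1 (harmonic mean of the class's own
#' precision and recall), true-negative rate; their unweighted macro
#' averages; overall accuracy (`trace / total`); and Cohen's kappa
#' `(po - pe) / (1 - pe)` with `pe = sum_i row_i * col_i / total^2`.
#' Ratios with zero denominator are reported as 0 and flagged in the
#' `undefined` column rather than returned as `NaN`.
#'
#' @param cm A [confusion_matrix()].
#' @param drop_unclassified If `TRUE`, unclassified predictions are removed
#'   from all denominators; by default they count as errors.
#' @return A list of class `metrics_report`: `per_class` data frame,
#'   `macro` named vector (recall/precision/f1), `overall_accuracy`,
#'   `kappa`, `n`.
#' @export
classification_metrics <- function(cm, drop_unclassified = FALSE) {
  stopifnot(inherits(cm, "confusion_matrix"))
  classes <- rownames(cm)
  K <- length(classes)
  counts <- cm[, seq_len(K), drop = FALSE]
  n_uncl <- if (ncol(cm) > K) sum(cm[, K + 1L]) else 0L
  total <- sum(counts) + if (drop_unclassified) 0L else n_uncl
  if (total == 0) stop("empty confusion matrix")
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  tp <- diag(counts)
  row_tot <- rowSums(cm[, , drop = FALSE]) # includes unclassified as FN
  if (drop_unclassified) row_tot <- rowSums(counts)
  col_tot <- colSums(counts)
  recall <- safe_div(tp, row_tot)
  precision <- safe_div(tp, col_tot)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  tn <- total - row_tot - col_tot + tp
  tnr <- safe_div(tn, tn + (col_tot - tp))
  undefined <- row_tot == 0 | col_tot == 0 | (precision + recall) == 0
  po <- sum(tp) / total
  pe <- sum(as.numeric(row_tot) * as.numeric(col_tot)) / total^2
  kappa <- if (abs(1 - pe) < 1e-15) 0 else (po - pe) / (1 - pe)
  per_class <- data.frame(
    class = classes, recall = recall, precision = precision, f1 = f1,
    tpr = recall, tnr = tnr, undefined = undefined,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(per_class = per_class,
         macro = c(recall = mean(recall), precision = mean(precision),
                   f1 = mean(f1)),
         overall_accuracy = po, kappa = kappa, n = total,
         n_unclassified = n_uncl),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d, OA = %.4f, kappa = %.4f\n",
              x$n, x$overall_accuracy, x$kappa))
  print(cbind(x$per_class[1],
              round(x$per_class[, c("recall", "precision", "f1", "tnr")], 3)))
  cat(sprintf("macro: recall %.3f, precision %.3f, f1 %.3f\n",
              x$macro["recall"], x$macro["precision"], x$macro["f1"]))
  invisible(x)
}

#' F1 score from precision and recall
#'
#' `2PR / (P + R)`, defined as 0 when both are 0. Exposed because published
#' accuracy tables are checked for internal consistency by recomputing F1
#' from their printed precision and recall.
#'
#' @param precision,recall Numeric vectors in the unit interval.
#' @return Numeric vector of F1 values.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Write a metrics report as CSV
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @export
write_metrics_csv <- function(report, path) {
  df <- report$per_class
  df$overall_accuracy <- report$overall_accuracy
  df$kappa <- report$kappa
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
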
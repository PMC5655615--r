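## Confusion-matrix construction and the six standard threshold metrics
## for binder/non-binder classification models.

#' Confusion counts for binary labels
#'
#' @param trueLabels binary (0/1) vector of reference labels; 1 is the
#'   positive ("binder") class.
#' @param predictedLabels binary (0/1) vector of predictions, same
#'   length.
#' @return a [ConfusionCounts-class].
#' @examples
#' confusionCounts(rep(c(1, 0), c(5, 5)), rep(c(1, 0), c(5, 5)))
#' @export
confusionCounts <- function(trueLabels, predictedLabels) {
  if (length(trueLabels) != length(predictedLabels)) stop("length mismatch")
  t <- as.integer(trueLabels); p <- as.integer(predictedLabels)
  if (!all(t %in% c(0L, 1L)) || !all(p %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  new("ConfusionCounts",
      tp = sum(t == 1L & p == 1L), tn = sum(t == 0L & p == 0L),
      fp = sum(t == 0L & p == 1L), fn = sum(t == 1L & p == 0L))
}

#' The six threshold classification metrics
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`,
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, fall-out
#' `1 - SPEC`, and F1 `2TP/(2TP+FP+FN)`.  Metrics with a zero
#' denominator are `NaN` rather than 0.  F1 is computed from the counts;
#' whenever precision and sensitivity are both defined this equals
#' `2*PREC*SENS/(PREC+SENS)` exactly.
#'
#' @param counts a [ConfusionCounts-class] (or a list/vector with
#'   elements `tp`, `tn`, `fp`, `fn`).
#' @return named numeric vector `acc`, `prec`, `sens`, `spec`, `fall`,
#'   `f1`, each in `[0, 1]` or `NaN`.
#' @examples
#' classificationMetrics(confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1)))
#' @export
classificationMetrics <- function(counts) {
  if (is(counts, "ConfusionCounts")) {
    tp <- counts@tp; tn <- counts@tn; fp <- counts@fp; fn <- counts@fn
  } else {
    tp <- counts[["tp"]]; tn <- counts[["tn"]]
    fp <- counts[["fp"]]; fn <- counts[["fn"]]
  }
  tot <- tp + tn + fp + fn
  if (tot == 0) stop("all counts are zero")
  ratio <- function(num, den) if (den == 0) NaN else num / den
  spec <- ratio(tn, tn + fp)
  c(acc = ratio(tp + tn, tot),
    prec = ratio(tp, tp + fp),
    sens = ratio(tp, tp + fn),
    spec = spec,
    fall = 1 - spec,
    f1 = ratio(2 * tp, 2 * tp + fp + fn))
}
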
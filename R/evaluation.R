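#' Confusion counts
#'
#' @param y true 0/1 labels.
#' @param yhat predicted 0/1 labels, same length.
#' @return list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat differ in length")
  y <- as.logical(y)
  yhat <- as.logical(yhat)
  list(TP = sum(y & yhat), FP = sum(!y & yhat),
       TN = sum(!y & !yhat), FN = sum(y & !yhat))
}

#' Dichotomous metrics
#'
#' `recall = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `ppv = TP / (TP + FP)`, `npv = TN / (TN + FN)`. A zero denominator raises
#' an undefined-metric error.
#'
#' @param counts list from [confusion()].
#' @return fraction in `[0, 1]`.
#' @export
recall <- function(counts) {
  d <- counts$TP + counts$FN
  if (d == 0) stop("recall undefined: no positives")
  counts$TP / d
}

#' @rdname recall
#' @export
specificity <- function(counts) {
  d <- counts$TN + counts$FP
  if (d == 0) stop("specificity undefined: no negatives")
  counts$TN / d
}

#' @rdname recall
#' @export
ppv_npv <- function(counts) {
  if (counts$TP + counts$FP == 0) stop("PPV undefined: no positive calls")
  if (counts$TN + counts$FN == 0) stop("NPV undefined: no negative calls")
  c(ppv = counts$TP / (counts$TP + counts$FP),
    npv = counts$TN / (counts$TN + counts$FN))
}

#' Balanced accuracy
#'
#' @param recall,specificity values in `[0, 1]`.
#' @return `(recall + specificity) / 2`.
#' @export
balanced_accuracy <- function(recall, specificity) {
  stopifnot(recall >= 0, recall <= 1, specificity >= 0, specificity <= 1)
  (recall + specificity) / 2
}

#' Area under the ROC curve
#'
#' Rank-based (Wilcoxon) estimate with midranks for ties: the probability that
#' a random positive outscores a random negative, counting ties as 1/2.
#'
#' @param scores numeric scores.
#' @param y binary labels, both classes present.
#' @return AUC in `[0, 1]`; 0.5 for label-independent scores.
#' @export
auc <- function(scores, y) {
  y <- as.logical(y)
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("AUC undefined with a single class")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Adjusted positive predictive value
#'
#' PPV after reclassifying a given number of false positives as true
#' positives: `(TP + reclassified) / (TP + FP)`.
#'
#' @param counts list from [confusion()] (or with `TP`, `FP`).
#' @param reclassified non-negative count, at most `FP`.
#' @return adjusted PPV.
#' @export
adjusted_ppv <- function(counts, reclassified) {
  if (reclassified < 0 || reclassified > counts$FP) {
    stop("reclassified must lie in [0, FP]")
  }
  (counts$TP + reclassified) / (counts$TP + counts$FP)
}

#' Standard metric panel for a score vector
#'
#' @param scores predicted probabilities.
#' @param y binary labels.
#' @param threshold classification threshold (score >= threshold is positive).
#' @return named list of auc, recall, specificity, bacc, ppv, npv.
#' @export
metric_panel <- function(scores, y, threshold) {
  cts <- confusion(y, scores >= threshold)
  re <- recall(cts)
  sp <- specificity(cts)
  pn <- ppv_npv(cts)
  list(auc = auc(scores, y), recall = re, specificity = sp,
       bacc = balanced_accuracy(re, sp),
       ppv = unname(pn["ppv"]), npv = unname(pn["npv"]),
       counts = cts)
}
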
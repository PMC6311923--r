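# Evaluation statistics: confusion counts, sensitivity/specificity/accuracy/
# Matthews correlation coefficient, and ROC AUC (rank statistic, ties half).

#' Confusion counts from scores
#'
#' Thresholds positive-class scores: a score greater than or equal to
#' \code{threshold} predicts positive (ties are called positive).
#'
#' @param scores positive-class probabilities in [0, 1].
#' @param labels binary labels (1/TRUE = positive).
#' @param threshold score cutoff.
#' @return a \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0L) stop("no samples", call. = FALSE)
  stopifnot(length(scores) == length(labels),
            all(scores >= 0 & scores <= 1))
  y <- as.integer(as.logical(labels))
  pred <- as.integer(scores >= threshold)
  new("ConfusionCounts",
      tp = sum(pred == 1L & y == 1L), fn = sum(pred == 0L & y == 1L),
      tn = sum(pred == 0L & y == 0L), fp = sum(pred == 1L & y == 0L))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: Tp=%d Fn=%d Tn=%d Fp=%d\n",
              object@tp, object@fn, object@tn, object@fp))
})

#' Classification metrics from confusion counts
#'
#' Sensitivity Sn = Tp/(Tp+Fn), specificity Sp = Tn/(Tn+Fp), accuracy
#' ACC = (Tp+Tn)/n, and the Matthews correlation coefficient
#' MCC = (Tp*Tn - Fp*Fn) / sqrt((Tn+Fn)(Tn+Fp)(Tp+Fn)(Tp+Fp)).
#' When any factor of the MCC denominator is zero the MCC is reported as 0
#' (the usual convention). Requires at least one sample of each class.
#'
#' @param counts a \linkS4class{ConfusionCounts}, or scores given with
#'   \code{labels}.
#' @param labels,threshold when \code{counts} is a score vector, the labels
#'   and cutoff handed to \code{\link{confusionCounts}}.
#' @param auc optional AUC to carry into the report.
#' @return a \linkS4class{MetricsReport}.
#' @examples
#' cc <- new("ConfusionCounts", tp = 9L, fn = 1L, tn = 8L, fp = 2L)
#' classificationMetrics(cc)   # Sn 0.9, Sp 0.8, ACC 0.85, MCC ~ 0.7035
#' @export
classificationMetrics <- function(counts, labels = NULL, threshold = 0.5,
                                  auc = NA_real_) {
  if (!is(counts, "ConfusionCounts"))
    counts <- confusionCounts(counts, labels, threshold)
  tp <- as.numeric(counts@tp); fn <- as.numeric(counts@fn)
  tn <- as.numeric(counts@tn); fp <- as.numeric(counts@fp)
  if (tp + fn == 0)
    stop("sensitivity undefined: no positive samples", call. = FALSE)
  if (tn + fp == 0)
    stop("specificity undefined: no negative samples", call. = FALSE)
  den <- (tn + fn) * (tn + fp) * (tp + fn) * (tp + fp)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  new("MetricsReport",
      sn = tp / (tp + fn), sp = tn / (tn + fp),
      acc = (tp + tn) / (tp + fn + tn + fp),
      mcc = mcc, auc = auc, threshold = threshold, counts = counts)
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (threshold %.2f):\n", object@threshold))
  cat(sprintf("  Sn %.4f  Sp %.4f  ACC %.4f  MCC %.4f  AUC %s\n",
              object@sn, object@sp, object@acc, object@mcc,
              if (is.na(object@auc)) "NA" else sprintf("%.4f", object@auc)))
})

#' Area under the ROC curve
#'
#' The probability that a random positive outscores a random negative, ties
#' counting one half — computed as the Wilcoxon rank statistic, which equals
#' trapezoidal integration of the ROC curve over all distinct thresholds.
#'
#' @param scores positive-class scores.
#' @param labels binary labels (1/TRUE = positive); both classes must be
#'   present.
#' @return AUC in [0, 1].
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))   # 0.75
#' @export
rocAuc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' ROC curve points
#'
#' False/true positive rates at every distinct score threshold (descending),
#' with the (0,0) and (1,1) endpoints.
#'
#' @inheritParams rocAuc
#' @return data.frame with columns \code{threshold}, \code{fpr}, \code{tpr}.
#' @export
rocCurve <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC undefined: both classes must be present", call. = FALSE)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & y == 1L) / nPos, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & y == 0L) / nNeg, numeric(1))
  data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Score fragments with a model
#'
#' Extracts, encodes and scores variable-length fragments, batching by
#' length so each forward pass satisfies the equal-length batch contract.
#'
#' @param model a \linkS4class{DHSModel}.
#' @param genome a \code{DNAStringSet}.
#' @param intervals a \code{GRanges}.
#' @param batchSize maximum samples per forward pass.
#' @return numeric vector of DHS probabilities, parallel to
#'   \code{intervals}.
#' @export
scoreFragments <- function(model, genome, intervals, batchSize = 128L) {
  seqs <- extractFragments(genome, intervals)
  lens <- nchar(seqs)
  scores <- numeric(length(seqs))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    for (chunk in split(idx, ceiling(seq_along(idx) / batchSize))) {
      X <- array(0, c(4L, L, length(chunk)))
      for (i in seq_along(chunk)) X[, , i] <- t(oneHotEncode(seqs[chunk[i]]))
      scores[chunk] <- predict(model, X)[, "DHS"]
    }
  }
  scores
}

#' Evaluate a model on a labeled interval set
#'
#' Scores the fragments and reports the full metrics (Sn, Sp, ACC, MCC at
#' the given threshold, plus AUC).
#'
#' @param model a \linkS4class{DHSModel}.
#' @param genome a \code{DNAStringSet}.
#' @param intervals a \code{GRanges} with a \code{label} metadata column.
#' @param threshold positive-call cutoff.
#' @param batchSize maximum samples per forward pass.
#' @return a \linkS4class{MetricsReport}.
#' @export
evaluateModel <- function(model, genome, intervals, threshold = 0.5,
                          batchSize = 128L) {
  lab <- mcols(intervals)$label
  if (is.null(lab)) stop("intervals need a 'label' metadata column",
                         call. = FALSE)
  y <- as.integer(lab == "positive")
  scores <- scoreFragments(model, genome, intervals, batchSize)
  classificationMetrics(scores, y, threshold, auc = rocAuc(scores, y))
}
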
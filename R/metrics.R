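#' Confusion-matrix classification metrics
#'
#' Tabulates a binary prediction against truth and returns counts plus
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) and accuracy.
#'
#' @param truth 0/1 vector of true labels (1 = positive).
#' @param predicted 0/1 vector of predicted labels, same length.
#' @return A list of class `classification_metrics` with elements `tp`,
#'   `fp`, `tn`, `fn`, `n`, `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(truth, predicted) {
  truth <- as.numeric(truth)
  predicted <- as.numeric(predicted)
  if (length(truth) == 0L) stop("empty label vectors", call. = FALSE)
  if (length(truth) != length(predicted)) {
    stop("'truth' and 'predicted' must have equal length", call. = FALSE)
  }
  check_binary(truth, "truth")
  check_binary(predicted, "predicted")
  if (all(truth == 1)) {
    stop("degenerate truth: no negative cases present", call. = FALSE)
  }
  if (all(truth == 0)) {
    stop("degenerate truth: no positive cases present", call. = FALSE)
  }
  tp <- sum(truth == 1 & predicted == 1)
  fp <- sum(truth == 0 & predicted == 1)
  tn <- sum(truth == 0 & predicted == 0)
  fn <- sum(truth == 1 & predicted == 0)
  n <- length(truth)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / n),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("n = %d  (TP %d, FP %d, TN %d, FN %d)\n",
              x$n, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy))
  invisible(x)
}

# shared input checks for ROC-type functions
check_roc_input <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) {
    stop("'scores' and 'labels' must have equal length", call. = FALSE)
  }
  if (length(scores) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("'scores' must be finite", call. = FALSE)
  }
  check_binary(labels, "labels")
  if (all(labels == 1) || all(labels == 0)) {
    stop("ROC requires at least one positive and one negative label",
         call. = FALSE)
  }
  list(scores = scores, labels = labels)
}

#' Receiver operating characteristic curve
#'
#' Sweeps the classification threshold over every distinct score (predicted
#' positive when score >= threshold), producing a curve from (0, 0) to
#' (1, 1), and integrates the area under it by the trapezoidal rule. The
#' trapezoidal AUROC equals the Mann-Whitney statistic
#' P(score_pos > score_neg) + P(tie)/2, which the test-suite verifies by
#' brute force. The Youden-optimal cutoff (maximizing
#' J = sensitivity + specificity - 1, ties broken towards the larger cutoff)
#' is returned alongside.
#'
#' @param scores Numeric scores; higher means more positive-like.
#' @param labels 0/1 truth, at least one of each class.
#' @return A list of class `roc_curve` with `points` (data.frame of
#'   `threshold`, `fpr`, `tpr`), `auc`, `youden_cutoff`, `youden_j`.
#' @export
roc_curve <- function(scores, labels) {
  inp <- check_roc_input(scores, labels)
  scores <- inp$scores
  labels <- inp$labels
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  npos <- sum(y == 1)
  nneg <- sum(y == 0)
  # last index of each tied block of scores = cumulative counts at that threshold
  idx <- cumsum(rle(s)$lengths)
  tpr <- cumsum(y)[idx] / npos
  fpr <- cumsum(1 - y)[idx] / nneg
  thr <- s[idx]
  pts <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fpr),
                    tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  j <- tpr - fpr
  # ties on J (within numerical noise) break towards the larger cutoff:
  # thresholds are sorted decreasing, so take the first within tolerance
  best <- which(j >= max(j) - 1e-12)[1]
  structure(list(points = pts,
                 auc = auc,
                 youden_cutoff = thr[best],
                 youden_j = j[best]),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, AUROC = %.4f\n",
              nrow(x$points) - 1L, x$auc))
  cat(sprintf("Youden-optimal cutoff %.6g (J = %.4f)\n",
              x$youden_cutoff, x$youden_j))
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Returns the observed score maximizing J = sensitivity + specificity - 1
#' under the >=-cutoff rule, ties broken towards the larger cutoff (higher
#' specificity).
#'
#' @inheritParams roc_curve
#' @return A list with `cutoff` and `j`.
#' @export
youden_optimal_cutoff <- function(scores, labels) {
  r <- roc_curve(scores, labels)
  list(cutoff = r$youden_cutoff, j = r$youden_j)
}
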
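# ROC metrics: Mann-Whitney AUC, Youden-index thresholding, confusion
# formulas.

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' Probability that a random malignant score exceeds a random benign one,
#' ties counted one half; equals the area under the ROC curve and is
#' invariant under strictly increasing transforms of the scores.
#'
#' @param scores numeric classifier scores (higher = more malignant).
#' @param labels binary labels (1 = malignant).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Confusion-matrix performance measures
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)` and
#' specificity `TN/(TN+FP)`, as percentages.
#'
#' @param tp,fn,tn,fp confusion counts (positives = malignant).
#' @return named vector `accuracy`, `sensitivity`, `specificity` in percent.
#' @export
#' @examples
#' confusion_metrics(tp = 38, fn = 5, tn = 15, fp = 0)
confusion_metrics <- function(tp, fn, tn, fp) {
  c(accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp))
}

#' Youden-index optimal threshold and its operating point
#'
#' Sweeps candidate thresholds (midpoints between adjacent distinct scores,
#' plus minus/plus infinity), classifying as malignant where
#' `score > threshold`, and picks the threshold maximizing Youden's
#' `J = sensitivity + specificity - 1`; J ties are broken by accuracy, then
#' by the lower threshold. If every score is identical the ROC is flat
#' (J = 0) and the degenerate threshold is returned with a warning.
#'
#' @inheritParams auc
#' @return list with `threshold`, `J`, and `accuracy`, `sensitivity`,
#'   `specificity` in percent.
#' @export
youden_metrics <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("Youden metrics undefined: both classes must be present",
         call. = FALSE)
  }
  s <- sort(unique(scores))
  cand <- if (length(s) > 1) {
    c(-Inf, (s[-1] + s[-length(s)]) / 2, Inf)
  } else {
    warning("all scores identical: flat ROC, J = 0", call. = FALSE)
    c(-Inf, Inf)
  }
  best <- NULL
  for (thr in cand) {
    pred <- scores > thr
    tp <- sum(pred & labels == 1L)
    fp <- sum(pred & labels == 0L)
    fn <- npos - tp
    tn <- nneg - fp
    sens <- tp / npos
    spec <- tn / nneg
    j <- sens + spec - 1
    acc <- (tp + tn) / (npos + nneg)
    if (is.null(best) || j > best$J + 1e-12 ||
        (abs(j - best$J) <= 1e-12 && acc > best$acc_frac + 1e-12)) {
      best <- list(threshold = thr, J = j, acc_frac = acc,
                   accuracy = 100 * acc, sensitivity = 100 * sens,
                   specificity = 100 * spec)
    }
  }
  best$acc_frac <- NULL
  best
}
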
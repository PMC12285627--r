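#' @name threshold-metrics
#' @title Confusion-matrix metrics, ROC/PR curves and threshold selection
#' @description Classification of genes as predicted positives uses the rule
#'   score >= threshold. Sensitivity, specificity, precision, accuracy and
#'   F1 follow the usual confusion-matrix definitions; metrics with a zero
#'   denominator are flagged `NA` rather than forced to 0. AUROC is the
#'   normalized Mann-Whitney U statistic (ties count one half); AUPRC is the
#'   step-wise average precision with no interpolation.
NULL

check_scores_labels <- function(scores, labels) {
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0, 1)), all(is.finite(scores)))
  invisible(NULL)
}

#' Confusion counts at a threshold
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 true labels aligned with `scores`.
#' @param threshold decision threshold; predicted positive iff
#'   `score >= threshold`.
#' @return list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(scores, labels, threshold) {
  check_scores_labels(scores, labels)
  pred <- scores >= threshold
  list(TP = sum(pred & labels == 1), FP = sum(pred & labels == 0),
       TN = sum(!pred & labels == 0), FN = sum(!pred & labels == 1))
}

#' Metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, accuracy `(TP+TN)/n` and F1 (harmonic mean of precision and
#' sensitivity). Zero denominators yield `NA`.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` (as from [confusion()]).
#' @return list with `sensitivity`, `specificity`, `precision`, `accuracy`,
#'   `f1`.
#' @export
classification_metrics <- function(counts) {
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(counts$TP, counts$TP + counts$FN)
  spec <- safe_div(counts$TN, counts$TN + counts$FP)
  prec <- safe_div(counts$TP, counts$TP + counts$FP)
  acc <- safe_div(counts$TP + counts$TN,
                  counts$TP + counts$TN + counts$FP + counts$FN)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  list(sensitivity = sens, specificity = spec, precision = prec,
       accuracy = acc, f1 = f1)
}

#' F1 from precision and sensitivity
#'
#' @param precision,sensitivity values in `[0, 1]`.
#' @return `2 * precision * sensitivity / (precision + sensitivity)`; `NA`
#'   when both are 0.
#' @export
f1_score <- function(precision, sensitivity) {
  ifelse(precision + sensitivity == 0, NA_real_,
         2 * precision * sensitivity / (precision + sensitivity))
}

#' Area under the ROC curve
#'
#' Normalized Mann-Whitney U: the probability a random positive scores above
#' a random negative, ties counting one half.
#'
#' @param scores prediction scores.
#' @param labels 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUROC needs both classes", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: the sum over positives, walked in decreasing
#' score order, of precision at each recall step (no interpolation). Tied
#' scores are handled as one block so the result is permutation invariant.
#'
#' @param scores prediction scores.
#' @param labels 0/1 labels.
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || all(labels == 1)) {
    stop("AUPRC needs both classes", call. = FALSE)
  }
  # per unique threshold (descending): cumulative TP and predicted count
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  tp <- cumsum(y)
  np <- seq_along(y)
  last <- c(s[-1L] != s[-length(s)], TRUE)  # block ends of tied scores
  tp_b <- tp[last]
  np_b <- np[last]
  prec <- tp_b / np_b
  rec <- tp_b / n_pos
  d_rec <- diff(c(0, rec))
  sum(prec * d_rec)
}

#' ROC curve points
#'
#' @param scores prediction scores.
#' @param labels 0/1 labels.
#' @return data.frame with `threshold`, `fpr`, `tpr`, one row per unique
#'   score (descending) plus the all-negative point.
#' @export
roc_curve <- function(scores, labels) {
  check_scores_labels(scores, labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    cc <- confusion(scores, labels, t)
    c(fpr = cc$FP / (cc$FP + cc$TN), tpr = cc$TP / (cc$TP + cc$FN))
  }, c(fpr = 0, tpr = 0)))
  data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' Precision-recall curve points
#'
#' @param scores prediction scores.
#' @param labels 0/1 labels.
#' @return data.frame with `threshold`, `recall`, `precision`, one row per
#'   unique score (descending).
#' @export
pr_curve <- function(scores, labels) {
  check_scores_labels(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    cc <- confusion(scores, labels, t)
    c(recall = cc$TP / (cc$TP + cc$FN),
      precision = if (cc$TP + cc$FP == 0) NA_real_ else {
        cc$TP / (cc$TP + cc$FP)
      })
  }, c(recall = 0, precision = 0)))
  data.frame(threshold = thr, recall = pts[, "recall"],
             precision = pts[, "precision"])
}

#' Maximum-F1 decision threshold
#'
#' Scans the unique observed scores and selects the threshold maximizing F1;
#' ties go to the larger threshold (higher specificity).
#'
#' @param scores prediction scores.
#' @param labels 0/1 labels.
#' @return list with `threshold`, `criterion = "max_f1"` and `achieved`
#'   metrics at the selected threshold.
#' @export
max_f1_threshold <- function(scores, labels) {
  check_scores_labels(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  f1s <- vapply(thr, function(t) {
    f <- classification_metrics(confusion(scores, labels, t))$f1
    if (is.na(f)) -Inf else f
  }, numeric(1L))
  best <- thr[which.max(f1s)]  # first index = largest threshold on ties
  list(threshold = best, criterion = "max_f1",
       achieved = classification_metrics(confusion(scores, labels, best)))
}

#' Neyman-Pearson decision threshold
#'
#' Smallest candidate threshold (unique scores plus `+Inf`) whose empirical
#' false-positive rate on the supplied negatives does not exceed `alpha`.
#' This controls the type-I error empirically instead of optimizing a
#' combined score.
#'
#' @param scores prediction scores.
#' @param labels 0/1 labels (the negatives define the FPR).
#' @param alpha target false-positive rate (default 0.05).
#' @return list with `threshold`, `criterion = "neyman_pearson"`, `alpha`
#'   and `achieved` metrics at the selected threshold.
#' @export
np_threshold <- function(scores, labels, alpha = 0.05) {
  check_scores_labels(scores, labels)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  n_neg <- sum(labels == 0)
  if (n_neg < ceiling(1 / alpha)) {
    warning(sprintf(
      "only %d negatives; FPR control at alpha=%g is coarse", n_neg, alpha))
  }
  thr <- c(sort(unique(scores)), Inf)
  neg <- scores[labels == 0]
  for (t in thr) {
    if (mean(neg >= t) <= alpha) {
      return(list(threshold = t, criterion = "neyman_pearson", alpha = alpha,
                  achieved = classification_metrics(
                    confusion(scores, labels, t))))
    }
  }
}
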
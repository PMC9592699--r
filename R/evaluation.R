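# Binary-classification evaluation: rank-based ROC AUC (with half credit for
# score ties, so AUC equals the Mann-Whitney concordance U / (n1 n0)),
# confusion-matrix metrics at a decision threshold, and a stratified
# percentile-bootstrap confidence interval for the AUC.

#' Rank-based ROC AUC
#'
#' @param scores numeric classifier scores
#' @param labels binary 0/1 labels (both classes present)
#' @return AUC in \[0, 1\]
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param scores,labels as in [roc_auc()]
#' @return data.frame with `threshold`, `fpr`, `tpr`, sorted by descending
#'   threshold
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & labels == 0L) / max(1L, sum(labels == 0L)),
      tpr = sum(pred & labels == 1L) / max(1L, sum(labels == 1L)))
  }, numeric(2)))
  data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' Confusion-matrix metrics from counts
#'
#' @param tp,fp,tn,fn confusion counts
#' @return list of class `afmtl_metrics`: counts plus precision, sensitivity
#'   (recall), specificity, accuracy and F1 (harmonic mean of precision and
#'   sensitivity); ratios with zero denominators are `NA`
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- ratio(tp, tp + fp)
  sensitivity <- ratio(tp, tp + fn)
  specificity <- ratio(tn, tn + fp)
  accuracy <- ratio(tp + tn, tp + fp + tn + fn)
  f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
            (precision + sensitivity) > 0)
    2 * precision * sensitivity / (precision + sensitivity) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, precision = precision,
                 sensitivity = sensitivity, specificity = specificity,
                 accuracy = accuracy, f1 = f1),
            class = "afmtl_metrics")
}

#' Threshold metrics for scored predictions
#'
#' @param scores numeric scores
#' @param labels binary 0/1 labels
#' @param threshold scores >= threshold predict class 1
#' @return an `afmtl_metrics` list (see [metrics_from_counts()])
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  metrics_from_counts(tp = sum(pred == 1L & labels == 1L),
                      fp = sum(pred == 1L & labels == 0L),
                      tn = sum(pred == 0L & labels == 0L),
                      fn = sum(pred == 0L & labels == 1L))
}

#' Stratified percentile-bootstrap confidence interval for the AUC
#'
#' Resamples positives and negatives separately with replacement;
#' degenerate resamples (a class missing) cannot occur under stratification.
#'
#' @param scores,labels as in [roc_auc()]
#' @param n_boot bootstrap replicates
#' @param level confidence level
#' @param seed RNG seed
#' @return list with `auc`, `ci_low`, `ci_high`
#' @export
auc_ci <- function(scores, labels, n_boot = 2000L, level = 0.95, seed = 0L) {
  labels <- as.integer(labels)
  i1 <- which(labels == 1L); i0 <- which(labels == 0L)
  if (!length(i1) || !length(i0)) stopf("AUC needs both classes present")
  point <- roc_auc(scores, labels)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    j1 <- sample(i1, length(i1), replace = TRUE)
    j0 <- sample(i0, length(i0), replace = TRUE)
    roc_auc(c(scores[j1], scores[j0]),
            c(rep(1L, length(j1)), rep(0L, length(j0))))
  }, numeric(1)))
  a <- (1 - level) / 2
  qs <- stats::quantile(boots, c(a, 1 - a), names = FALSE, type = 7)
  list(auc = point, ci_low = qs[1], ci_high = qs[2])
}

#' Full evaluation report for one cohort
#'
#' @param scores,labels predictions and truth
#' @param threshold decision threshold
#' @param n_boot,seed bootstrap settings for the AUC interval
#' @return list with auc, ci, and all threshold metrics
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5,
                            n_boot = 2000L, seed = 0L) {
  ci <- auc_ci(scores, labels, n_boot = n_boot, seed = seed)
  tm <- threshold_metrics(scores, labels, threshold)
  c(list(auc = ci$auc, ci_low = ci$ci_low, ci_high = ci$ci_high),
    unclass(tm))
}

#' @export
print.afmtl_metrics <- function(x, ...) {
  cat(sprintf(
    "confusion: TP=%d FP=%d TN=%d FN=%d\nprecision=%.4f sensitivity=%.4f specificity=%.4f accuracy=%.4f F1=%.4f\n",
    x$tp, x$fp, x$tn, x$fn, x$precision, x$sensitivity, x$specificity,
    x$accuracy, x$f1))
  invisible(x)
}
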
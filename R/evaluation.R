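#' Confusion counts
#'
#' Tallies true/false positives/negatives with antigen-positive as the
#' positive class. Pairs with a missing truth call are excluded (their count
#' is recorded in attribute `n_excluded`).
#'
#' @param truth,pred Call vectors of equal length.
#' @param positive Label of the positive class (default `"positive"`).
#' @return A list of class `confusion_counts` with integer fields `TP`,
#'   `TN`, `FP`, `FN`; they sum to the number of evaluated samples.
#' @export
confusion_counts <- function(truth, pred, positive = "positive") {
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  keep <- !is.na(truth)
  truth <- as.character(truth)[keep]
  pred <- as.character(pred)[keep]
  t_pos <- truth == positive
  p_pos <- pred == positive
  out <- structure(list(
    TP = sum(t_pos & p_pos), TN = sum(!t_pos & !p_pos),
    FP = sum(!t_pos & p_pos), FN = sum(t_pos & !p_pos)
  ), class = "confusion_counts")
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d | TN %d | FP %d | FN %d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Accuracy metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive and negative
#' predictive values `TP/(TP+FP)` and `TN/(TN+FN)`, and balanced accuracy
#' `(sensitivity + specificity)/2` — the imbalance-robust headline metric.
#' A metric whose denominator is zero is undefined and reported as `NA`;
#' balanced accuracy is `NA` if either recall is. A model with balanced
#' accuracy exactly 0.5 is flagged `"failed_classification"`.
#'
#' @param counts A [confusion_counts()] object.
#' @return One-row data frame: `TP`, `TN`, `FP`, `FN`, `sensitivity`,
#'   `specificity`, `PPV`, `NPV`, `balanced_accuracy`, `flag`.
#' @examples
#' # two of three antigen-positive samples recovered, no false positives:
#' m <- accuracy_metrics(confusion_counts(
#'   c(rep("positive", 3), rep("negative", 90)),
#'   c("positive", "positive", "negative", rep("negative", 90))))
#' m$balanced_accuracy  # 0.8333...
#' @export
accuracy_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rat <- function(a, b) if (a + b == 0L) NA_real_ else a / (a + b)
  sens <- rat(counts$TP, counts$FN)
  spec <- rat(counts$TN, counts$FP)
  ba <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  flag <- if (!is.na(ba) && ba == 0.5) "failed_classification" else ""
  data.frame(TP = counts$TP, TN = counts$TN, FP = counts$FP, FN = counts$FN,
             sensitivity = sens, specificity = spec,
             PPV = rat(counts$TP, counts$FP), NPV = rat(counts$TN, counts$FN),
             balanced_accuracy = ba, flag = flag, stringsAsFactors = FALSE)
}

#' One-vs-rest metric rows for a multi-class phenotype
#'
#' Derives one [accuracy_metrics()] row per class (e.g. the A, AB, B, O rows
#' of an ABO model), treating that class as antigen-positive and all others
#' as negative.
#'
#' @param truth,pred Multi-class call vectors.
#' @param classes Classes to report (default: observed truth classes).
#' @return Data frame with a `class` column followed by the metric columns.
#' @export
one_vs_rest_metrics <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(truth[!is.na(truth)])))
  rows <- lapply(classes, function(cl) {
    cc <- confusion_counts(truth, pred, positive = cl)
    cbind(class = cl, accuracy_metrics(cc), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' ROC and precision-recall curves
#'
#' Threshold sweep over the distinct posterior probabilities: each threshold
#' calls `PP >= t` positive. The area under the ROC curve is computed by the
#' trapezoid rule; the precision-recall curve reports precision at each
#' recall step with area by step-wise (rectangular) integration.
#'
#' @param pp Antigen-positive posterior probabilities.
#' @param truth Binary truth calls (both classes must be present).
#' @param positive Positive-class label.
#' @return A list of class `roc_pr`: `roc` (data frame `threshold`, `fpr`,
#'   `tpr`), `pr` (`threshold`, `recall`, `precision`), `auroc`, `aupr`.
#' @export
roc_pr_curves <- function(pp, truth, positive = "positive") {
  keep <- !is.na(truth) & !is.na(pp)
  pp <- pp[keep]
  truth <- as.character(truth)[keep]
  is_pos <- truth == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) stop("ROC needs both classes in the truth")

  ord <- order(pp, decreasing = TRUE)
  pp_s <- pp[ord]
  pos_s <- is_pos[ord]
  # cumulative counts at each distinct threshold (ties grouped)
  grp <- !duplicated(pp_s, fromLast = TRUE)  # last index of each tie block
  cum_tp <- cumsum(pos_s)[grp]
  cum_fp <- cumsum(!pos_s)[grp]
  thr <- pp_s[grp]

  tpr <- c(0, cum_tp / n_pos)
  fpr <- c(0, cum_fp / n_neg)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  recall <- cum_tp / n_pos
  precision <- cum_tp / (cum_tp + cum_fp)
  aupr <- sum(diff(c(0, recall)) * precision)

  structure(list(
    roc = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
    pr = data.frame(threshold = thr, recall = recall, precision = precision),
    auroc = auroc, aupr = aupr
  ), class = "roc_pr")
}

#' @export
print.roc_pr <- function(x, ...) {
  cat(sprintf("<roc_pr> AUROC %.4f | AUPR %.4f (%d thresholds)\n",
              x$auroc, x$aupr, nrow(x$pr)))
  invisible(x)
}

#' Median and interquartile range of per-model balanced accuracies
#'
#' Summarizes a set of models by the median and quartiles of their balanced
#' accuracies, using the linear-interpolation quantile convention (position
#' `0.25 * (n - 1) + 1`; exact order statistics when the position is
#' integral — as for the 33 models shared across cohort comparisons, where
#' the quartiles are the 9th, 17th and 25th order statistics).
#'
#' @param values Numeric vector of per-model balanced accuracies; `NA`s
#'   (models not available in a cohort) are dropped.
#' @return A list of class `summary_stats`: `median`, `q1`, `q3`,
#'   `n_models`.
#' @export
summarize_balanced_accuracy <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("no values to summarize")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(median = q[2], q1 = q[1], q3 = q[3], n_models = length(v)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> median %.3f [IQR %.3f-%.3f], n = %d\n",
              x$median, x$q1, x$q3, x$n_models))
  invisible(x)
}

#' Rank-sum comparison of two model sets
#'
#' Two-sample Mann-Whitney-Wilcoxon test on per-model balanced accuracies
#' (midranks for ties, normal approximation with tie and continuity
#' correction) — used to ask whether one set of models outperforms another
#' across a cohort.
#'
#' @param a,b Numeric vectors of per-model values (`NA`s dropped).
#' @param alternative Passed to [stats::wilcox.test()].
#' @return A list of class `model_set_comparison`: `statistic` (the
#'   rank-sum U for `a`), `p_value`, `n_a`, `n_b`, `alternative`.
#' @export
compare_model_sets <- function(a, b, alternative = "two.sided") {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) stop("both model sets must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = FALSE, correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # every observation tied: no evidence of a difference
  structure(list(statistic = unname(wt$statistic), p_value = p,
                 n_a = length(a), n_b = length(b), alternative = alternative),
            class = "model_set_comparison")
}

#' @export
print.model_set_comparison <- function(x, ...) {
  cat(sprintf("<model_set_comparison> U = %.1f, p = %.3g (n = %d vs %d)\n",
              x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}
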
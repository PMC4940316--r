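#' Label candidates against annotated peak locations
#'
#' A candidate is a true peak when its peak index lies within `tolerance`
#' samples of an annotated location; each annotated location claims at most
#' one candidate (the nearest by peak index, ties going to the earlier
#' candidate), so duplicate detections of one peak are not double-counted.
#'
#' @param cands Candidate data.frame from [detect_candidates()], or an
#'   integer vector of candidate peak indices.
#' @param truth Integer vector of annotated peak indices.
#' @param tolerance Non-negative matching tolerance in samples; the default 5
#'   is about 20 ms at 256 Hz.
#' @return Logical vector, one element per candidate.
#' @export
match_candidates_to_truth <- function(cands, truth, tolerance = 5L) {
  pp <- if (is.data.frame(cands)) cands$pp else as.integer(cands)
  if (tolerance < 0) stop("'tolerance' must be >= 0", call. = FALSE)
  labels <- rep(FALSE, length(pp))
  taken <- rep(FALSE, length(pp))
  for (t in truth) {
    d <- abs(pp - t)
    d[taken | d > tolerance] <- NA
    if (all(is.na(d))) next
    k <- which(d == min(d, na.rm = TRUE))[1L]  # tie -> earlier candidate
    labels[k] <- TRUE
    taken[k] <- TRUE
  }
  labels
}

#' Confusion counts with "peak" as the positive class
#'
#' @param pred Predicted labels (logical or 0/1, 1 = peak).
#' @param truth True labels, same length and coding.
#' @return A list of class `confusion_counts` with integers `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (length(pred) != length(truth)) {
    stop("'pred' and 'truth' must have equal length", call. = FALSE)
  }
  structure(list(
    tp = sum(pred & truth), tn = sum(!pred & !truth),
    fp = sum(pred & !truth), fn = sum(!pred & truth)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Geometric-mean accuracy for imbalanced two-class results
#'
#' `G_mean = sqrt(TPR * TNR)` with `TPR = TP/(TP+FN)` (true-peak rate) and
#' `TNR = TN/(TN+FP)` (true-non-peak rate). The geometric mean punishes a
#' classifier that sacrifices the rare peak class: it is 0 whenever no true
#' peak is recovered, however many non-peaks are correct.
#'
#' @param counts A `confusion_counts` object.
#' @return G_mean in [0, 1].
#' @export
g_mean <- function(counts) {
  if (counts$tp + counts$fn == 0) {
    stop("no positive (peak) examples present", call. = FALSE)
  }
  if (counts$tn + counts$fp == 0) {
    stop("no negative (non-peak) examples present", call. = FALSE)
  }
  tpr <- counts$tp / (counts$tp + counts$fn)
  tnr <- counts$tn / (counts$tn + counts$fp)
  sqrt(tpr * tnr)
}

#' Sensitivity and specificity as percentages
#'
#' `sensitivity = TP/(TP+FN) * 100`, `specificity = TN/(TN+FP) * 100`.
#'
#' @param counts A `confusion_counts` object.
#' @return Named numeric vector `c(sensitivity, specificity)` in [0, 100].
#' @export
sensitivity_specificity <- function(counts) {
  if (counts$tp + counts$fn == 0) {
    stop("no positive (peak) examples present", call. = FALSE)
  }
  if (counts$tn + counts$fp == 0) {
    stop("no negative (non-peak) examples present", call. = FALSE)
  }
  c(sensitivity = 100 * counts$tp / (counts$tp + counts$fn),
    specificity = 100 * counts$tn / (counts$tn + counts$fp))
}

#' Summarise G_mean over independent runs
#'
#' @param g_means Numeric vector of per-run G_mean values.
#' @return Named numeric vector with `average`, `max`, `min` and the sample
#'   (n-1) standard deviation `stdev`; a single run yields `stdev = 0` with a
#'   warning.
#' @export
summarize_runs <- function(g_means) {
  if (!length(g_means)) stop("no runs to summarise", call. = FALSE)
  s <- if (length(g_means) > 1L) stats::sd(g_means) else {
    warning("single run: standard deviation undefined, reporting 0")
    0
  }
  c(average = mean(g_means), max = max(g_means), min = min(g_means),
    stdev = s)
}

#' Friedman rank test across models
#'
#' Within each run (row), models are ranked by accuracy with rank 1 best and
#' ties receiving average ranks. Returns the average rank of each model and
#' the Friedman chi-square statistic
#' `12N / (k(k+1)) * (sum R_j^2 - k(k+1)^2 / 4)` on `k - 1` degrees of
#' freedom (the uncorrected form, as rank-based comparison suites print it).
#'
#' @param acc Numeric matrix, runs x models, higher = better; column names
#'   label the models.
#' @return List with `avg_ranks`, `statistic`, `df`, `p_value`.
#' @export
friedman_ranks <- function(acc) {
  acc <- as.matrix(acc)
  n <- nrow(acc); k <- ncol(acc)
  if (n < 2L || k < 2L) {
    stop("need at least 2 runs and 2 models", call. = FALSE)
  }
  ranks <- t(apply(acc, 1L, function(row) rank(-row)))  # 1 = best
  avg <- colMeans(ranks)
  names(avg) <- colnames(acc)
  stat <- 12 * n / (k * (k + 1)) * sum(avg^2) - 3 * n * (k + 1)
  list(avg_ranks = avg,
       statistic = stat,
       df = k - 1L,
       p_value = stats::pchisq(stat, df = k - 1L, lower.tail = FALSE))
}

#' Holm-Bonferroni step-down procedure
#'
#' Sorts the pairwise p-values ascending and compares the i-th smallest to
#' `alpha / (k - i + 1)`; rejection proceeds step-down and stops at the
#' first non-significant comparison. Rows are returned in the conventional
#' post-hoc table order, largest divisor (smallest p) first.
#'
#' @param pairwise_p Named numeric vector of p-values, one per model pair.
#' @param alpha Family-wise error level (e.g. 0.05 or 0.10).
#' @return A data.frame with columns `i` (divisor index, k..1), `pair`, `p`,
#'   `holm` (the threshold `alpha / i`) and `reject`.
#' @export
holm_posthoc <- function(pairwise_p, alpha = 0.05) {
  if (any(pairwise_p < 0 | pairwise_p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  k <- length(pairwise_p)
  ord <- order(pairwise_p)
  p <- pairwise_p[ord]
  divisor <- k:1L
  thresh <- alpha / divisor
  reject <- logical(k)
  for (j in seq_len(k)) {
    if (p[j] < thresh[j]) reject[j] <- TRUE else break
  }
  data.frame(i = divisor,
             pair = if (is.null(names(p))) as.character(seq_len(k)) else names(p),
             p = as.numeric(p),
             holm = thresh,
             reject = reject,
             row.names = NULL)
}

#' Pairwise Wilcoxon signed-rank p-values over runs
#'
#' Companion to [friedman_ranks()]: for every pair of models, a paired
#' Wilcoxon signed-rank test (normal approximation) on the per-run
#' accuracies. Pairs whose accuracies are identical in every run get p = 1.
#'
#' @param acc Numeric matrix, runs x models, with column names.
#' @return Named numeric vector of p-values, names like `"A vs. B"`.
#' @export
pairwise_wilcoxon <- function(acc) {
  acc <- as.matrix(acc)
  models <- colnames(acc)
  if (is.null(models)) models <- paste0("model", seq_len(ncol(acc)))
  pairs <- utils::combn(seq_len(ncol(acc)), 2L)
  p <- numeric(ncol(pairs))
  nm <- character(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    d <- acc[, a] - acc[, b]
    p[j] <- if (all(d == 0)) 1 else suppressWarnings(
      stats::wilcox.test(acc[, a], acc[, b], paired = TRUE,
                         exact = FALSE)$p.value)
    nm[j] <- paste(models[a], "vs.", models[b])
  }
  stats::setNames(p, nm)
}
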
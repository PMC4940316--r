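# Independent brute-force oracles used to cross-check the implementation.

# literal three-point scan of every interior triple (no plateau handling;
# used on tie-free signals)
brute_extrema <- function(x) {
  n <- length(x)
  interior <- 2:(n - 1L)
  list(
    maxima = interior[x[interior] > x[interior - 1L] & x[interior] > x[interior + 1L]],
    minima = interior[x[interior] < x[interior - 1L] & x[interior] < x[interior + 1L]]
  )
}

# tie-free random signal
random_signal <- function(len) stats::rnorm(len)

# Friedman chi-square from rank sums, straight from the textbook formula
friedman_oracle <- function(acc) {
  R <- t(apply(acc, 1L, function(row) rank(-row)))
  n <- nrow(acc); k <- ncol(acc)
  Rj <- colSums(R)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  list(statistic = stat,
       p_value = stats::pchisq(stat, k - 1L, lower.tail = FALSE))
}

# literal step-down enumeration of the Holm procedure
holm_oracle <- function(p, alpha) {
  k <- length(p)
  ps <- sort(p)
  reject <- logical(k)
  for (i in seq_len(k)) {
    if (ps[i] < alpha / (k - i + 1)) reject[i] <- TRUE else break
  }
  reject
}

# pairwise label comparison, counting one pair at a time
brute_confusion <- function(pred, truth) {
  counts <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (i in seq_along(pred)) {
    key <- if (pred[i] && truth[i]) "tp"
           else if (!pred[i] && !truth[i]) "tn"
           else if (pred[i] && !truth[i]) "fp"
           else "fn"
    counts[key] <- counts[key] + 1L
  }
  counts
}

# toy signal whose eight points and features were worked out by hand
toy_signal <- c(2, 0, 1, 3, 1, 0, 2)
toy_features <- c(f1 = 3, f2 = 3, f3 = 3, f4 = 3, f5 = 12 / 7,
                  f6 = 4, f7 = 2, f8 = 2, f9 = 4, f10 = 2, f11 = 2, f12 = 2,
                  f13 = 1.5, f14 = 1.5, f15 = 1.5, f16 = 1.5)
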
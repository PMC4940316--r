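#' Locate local maxima and minima with the three-point sliding window
#'
#' An interior sample is a peak point when it is strictly greater than both
#' neighbours, and a valley point when strictly smaller than both. Runs of
#' equal consecutive values (plateaus, common under quantisation) are first
#' collapsed to their first index, so a flat-topped peak yields exactly one
#' maximum. Signal endpoints are never returned as extrema.
#'
#' An optional prominence threshold `delta` (Billauer-style) discards maxima
#' that do not rise at least `delta` above the lower of their two flanking
#' collapsed neighbours; the default 0 disables it.
#'
#' @param signal An [eeg_signal] or numeric vector of at least 3 samples.
#' @param delta Non-negative prominence threshold; 0 keeps the pure
#'   three-point test.
#' @return List with sorted integer vectors `maxima` and `minima` (indices
#'   into the original samples).
#' @examples
#' find_extrema(c(2, 0, 1, 3, 1, 0, 2))  # maxima 4, minima 2 and 6
#' @export
find_extrema <- function(signal, delta = 0) {
  x <- signal_samples(signal)
  if (length(x) < 3L) stop("signal must have at least 3 samples", call. = FALSE)
  if (delta < 0) stop("'delta' must be non-negative", call. = FALSE)

  # collapse plateaus: keep the first index of each run of equal values
  keep <- c(TRUE, diff(x) != 0)
  idx <- which(keep)          # original index of each collapsed sample
  xc <- x[keep]
  n <- length(xc)
  if (n < 3L) return(list(maxima = integer(0), minima = integer(0)))

  interior <- 2:(n - 1L)
  d1 <- diff(xc)              # xc[i+1] - xc[i], never zero
  rising <- d1 > 0
  is_max <- rising[interior - 1L] & !rising[interior]
  is_min <- !rising[interior - 1L] & rising[interior]

  maxima <- interior[is_max]
  minima <- interior[is_min]

  if (delta > 0 && length(maxima)) {
    # topographic prominence: lowest drop on either side before a sample
    # exceeding the maximum is met (or the boundary)
    prom <- vapply(maxima, function(i) {
      lrange <- rev(seq_len(i - 1L))
      higher <- which(xc[lrange] > xc[i])
      if (length(higher)) lrange <- lrange[seq_len(higher[1L] - 1L)]
      left <- if (length(lrange)) min(xc[lrange]) else xc[i]
      rrange <- seq(i + 1L, n)
      higher <- which(xc[rrange] > xc[i])
      if (length(higher)) rrange <- rrange[seq_len(higher[1L] - 1L)]
      right <- if (length(rrange)) min(xc[rrange]) else xc[i]
      xc[i] - max(left, right)
    }, numeric(1))
    maxima <- maxima[prom >= delta]
  }

  list(maxima = idx[maxima], minima = idx[minima])
}

#' Assemble candidate peaks from extrema
#'
#' Each local maximum becomes a candidate peak `PP` flanked by its nearest
#' valley on each side: `VP1` to the left, `VP2` to the right. A maximum with
#' no interior valley on one side may use the signal boundary sample as its
#' valley, provided that boundary sample does not exceed the peak value
#' (`use_endpoints = TRUE`, the default); otherwise such maxima are dropped.
#'
#' @param signal An [eeg_signal] or numeric vector.
#' @param delta Prominence threshold passed to [find_extrema()].
#' @param use_endpoints Allow boundary samples to act as valleys.
#' @return A data.frame with columns `vp1`, `pp`, `vp2` (one row per
#'   candidate, sorted by `pp`) and attribute `n_dropped` counting maxima
#'   discarded for want of a flanking valley.
#' @examples
#' detect_candidates(c(2, 0, 1, 3, 1, 0, 2))
#' @export
detect_candidates <- function(signal, delta = 0, use_endpoints = TRUE) {
  x <- signal_samples(signal)
  ext <- find_extrema(x, delta = delta)
  maxima <- ext$maxima
  minima <- ext$minima
  L <- length(x)

  vp1 <- vp2 <- pp <- integer(0)
  dropped <- 0L
  for (p in maxima) {
    left <- minima[minima < p]
    right <- minima[minima > p]
    v1 <- if (length(left)) max(left) else NA_integer_
    v2 <- if (length(right)) min(right) else NA_integer_
    if (is.na(v1) && use_endpoints && x[1L] <= x[p] && p > 1L) v1 <- 1L
    if (is.na(v2) && use_endpoints && x[L] <= x[p] && p < L) v2 <- L
    if (is.na(v1) || is.na(v2)) {
      dropped <- dropped + 1L
      next
    }
    vp1 <- c(vp1, v1); pp <- c(pp, p); vp2 <- c(vp2, v2)
  }
  out <- data.frame(vp1 = vp1, pp = pp, vp2 = vp2)
  out <- out[order(out$pp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

# accept either an eeg_signal or a bare numeric vector
signal_samples <- function(signal) {
  if (inherits(signal, "eeg_signal")) signal$samples else as.numeric(signal)
}
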
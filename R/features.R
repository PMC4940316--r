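#' Moving-average curve
#'
#' Centered moving mean used as the slow baseline reference under a peak
#' (the MAC). Near the signal boundaries the window is truncated to the
#' samples that exist, so the output always has the input's length; a window
#' longer than the signal reduces every output to the global mean. A trailing
#' (causal) variant is available.
#'
#' @param signal An [eeg_signal] or numeric vector.
#' @param window Positive integer window length in samples (default 100).
#' @param align `"center"` (default) or `"trailing"`.
#' @return Numeric vector of the same length as the input.
#' @examples
#' moving_average(c(0, 3, 0), window = 1)   # identity
#' @export
moving_average <- function(signal, window = 100L, align = c("center", "trailing")) {
  x <- signal_samples(signal)
  align <- match.arg(align)
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("'window' must be >= 1", call. = FALSE)
  n <- length(x)
  i <- seq_len(n)
  if (align == "center") {
    lo <- pmax(1L, i - (window - 1L) %/% 2L)
    hi <- pmin(n, i + window %/% 2L)
  } else {
    lo <- pmax(1L, i - window + 1L)
    hi <- i
  }
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Locate the half point of a half wave
#'
#' The sample index nearest the midpoint between the peak point and a valley
#' point; an exact `.5` midpoint rounds toward the peak.
#'
#' @param pp Peak sample index.
#' @param vp Valley sample index on either side (`vp != pp`).
#' @return Integer index between `vp` and `pp`.
#' @export
locate_half_point <- function(pp, vp) {
  if (pp == vp) stop("'pp' and 'vp' must differ", call. = FALSE)
  mid <- (pp + vp) / 2
  as.integer(if (pp > vp) ceiling(mid) else floor(mid))
}

#' Locate the turning point of a half wave
#'
#' Walking from the peak toward the valley one sample at a time, the turning
#' point is the first sample at which the current one-step slope magnitude
#' falls to strictly less than half the preceding step's. When no step
#' qualifies before the valley is reached (including when peak and valley are
#' adjacent), the valley index is returned as fallback.
#'
#' @param signal An [eeg_signal] or numeric vector.
#' @param pp Peak sample index.
#' @param vp Valley sample index (`vp != pp`).
#' @return Integer index between `vp` and `pp`.
#' @export
locate_turning_point <- function(signal, pp, vp) {
  x <- signal_samples(signal)
  if (pp == vp) stop("'pp' and 'vp' must differ", call. = FALSE)
  step <- if (vp > pp) 1L else -1L
  if (abs(vp - pp) <= 1L) return(as.integer(vp))
  prev <- abs(x[pp] - x[pp + step])
  pos <- pp + step
  while (pos != vp) {
    cur <- abs(x[pos] - x[pos + step])
    if (cur < 0.5 * prev) return(as.integer(pos + step))
    prev <- cur
    pos <- pos + step
  }
  as.integer(vp)
}

#' Locate the eight characteristic points of a candidate peak
#'
#' Assembles, for one candidate, the peak point `PP`, flanking valleys `VP1`
#' and `VP2`, half points `HP1`/`HP2` (index midpoints of each half wave),
#' turning points `TP1`/`TP2` (slope-break points walking outward from the
#' peak), and the moving-average curve value at the peak index.
#'
#' @param signal An [eeg_signal] or numeric vector.
#' @param cand One candidate: a list or one-row data.frame with `vp1`, `pp`,
#'   `vp2` as produced by [detect_candidates()].
#' @param mac_window Moving-average window in samples (default 100).
#' @return A list of class `peak_points` with integer fields `pp`, `vp1`,
#'   `vp2`, `hp1`, `hp2`, `tp1`, `tp2` and numeric `mac_at_pp`.
#' @export
locate_points <- function(signal, cand, mac_window = 100L) {
  x <- signal_samples(signal)
  pp <- as.integer(cand$pp); vp1 <- as.integer(cand$vp1); vp2 <- as.integer(cand$vp2)
  stopifnot(vp1 < pp, pp < vp2, vp2 <= length(x))
  structure(list(
    pp = pp, vp1 = vp1, vp2 = vp2,
    hp1 = locate_half_point(pp, vp1),
    hp2 = locate_half_point(pp, vp2),
    tp1 = locate_turning_point(x, pp, vp1),
    tp2 = locate_turning_point(x, pp, vp2),
    mac_at_pp = moving_average(x, mac_window)[pp]
  ), class = "peak_points")
}

#' Compute the 16 time-domain peak features
#'
#' Evaluates the sixteen features of a candidate peak from its eight
#' characteristic points: five amplitudes (f1-f5, signal units), seven widths
#' (f6-f12, samples) and four slopes (f13-f16, signal units per sample). All
#' are absolute values, hence non-negative. Widths are reported in samples;
#' conversion to milliseconds via the sampling rate is a presentation
#' concern.
#'
#' \describe{
#'   \item{f1, f2}{peak-to-valley amplitude of the first / second half wave}
#'   \item{f3, f4}{peak-to-turning-point amplitude, first / second half wave}
#'   \item{f5}{amplitude of the peak above the moving-average curve}
#'   \item{f6}{full width, valley to valley (= f7 + f8)}
#'   \item{f7, f8}{half-wave widths, peak to each valley}
#'   \item{f9}{width between the two turning points}
#'   \item{f10, f11}{peak-to-turning-point widths}
#'   \item{f12}{width between the two half points}
#'   \item{f13, f14}{peak-to-valley slopes of each half wave}
#'   \item{f15, f16}{peak-to-turning-point slopes of each half wave}
#' }
#'
#' @param signal An [eeg_signal] or numeric vector.
#' @param pts A `peak_points` object from [locate_points()].
#' @return Named numeric vector `f1` .. `f16`.
#' @export
extract_features <- function(signal, pts) {
  y <- signal_samples(signal)
  p <- pts
  slope <- function(i, j) if (i == j) 0 else abs((y[i] - y[j]) / (i - j))
  f <- c(
    f1 = abs(y[p$pp] - y[p$vp1]),
    f2 = abs(y[p$pp] - y[p$vp2]),
    f3 = abs(y[p$pp] - y[p$tp1]),
    f4 = abs(y[p$pp] - y[p$tp2]),
    f5 = abs(y[p$pp] - p$mac_at_pp),
    f6 = abs(p$vp1 - p$vp2),
    f7 = abs(p$pp - p$vp1),
    f8 = abs(p$pp - p$vp2),
    f9 = abs(p$tp1 - p$tp2),
    f10 = abs(p$pp - p$tp1),
    f11 = abs(p$pp - p$tp2),
    f12 = abs(p$hp1 - p$hp2),
    f13 = slope(p$pp, p$vp1),
    f14 = slope(p$pp, p$vp2),
    f15 = slope(p$pp, p$tp1),
    f16 = slope(p$pp, p$tp2)
  )
  f
}

#' Feature matrix for a set of candidates
#'
#' Convenience wrapper: locates the eight points and computes all 16 features
#' for every candidate of a signal.
#'
#' @param signal An [eeg_signal] or numeric vector.
#' @param cands Candidate data.frame from [detect_candidates()]; computed on
#'   the fly when `NULL`.
#' @param mac_window Moving-average window in samples.
#' @return Numeric matrix, one row per candidate, columns `f1` .. `f16`, with
#'   the candidate peak indices as attribute `pp`.
#' @export
feature_matrix <- function(signal, cands = NULL, mac_window = 100L) {
  x <- signal_samples(signal)
  if (is.null(cands)) cands <- detect_candidates(x)
  mac <- moving_average(x, mac_window)
  out <- matrix(0, nrow = nrow(cands), ncol = 16L,
                dimnames = list(NULL, paste0("f", 1:16)))
  for (k in seq_len(nrow(cands))) {
    pp <- cands$pp[k]; vp1 <- cands$vp1[k]; vp2 <- cands$vp2[k]
    pts <- structure(list(
      pp = pp, vp1 = vp1, vp2 = vp2,
      hp1 = locate_half_point(pp, vp1),
      hp2 = locate_half_point(pp, vp2),
      tp1 = locate_turning_point(x, pp, vp1),
      tp2 = locate_turning_point(x, pp, vp2),
      mac_at_pp = mac[pp]
    ), class = "peak_points")
    out[k, ] <- extract_features(x, pts)
  }
  attr(out, "pp") <- cands$pp
  out
}

#' Peak-model registry
#'
#' The four published peak models, plus `all16`, as named subsets of the 16
#' features: Dumpala (f1, f6, f13, f14), Dingle (f5, f6, f13, f14), Acir
#' (f1, f2, f7, f8, f13, f14) and Liu (f1, f2, f3, f4, f6, f9, f12, f13,
#' f14, f15, f16).
#'
#' @param name One of `"dumpala"`, `"dingle"`, `"acir"`, `"liu"`, `"all16"`.
#' @return A list of class `peak_model` with fields `name` and `feature_ids`.
#' @examples
#' peak_model("dingle")$feature_ids
#' @export
peak_model <- function(name) {
  registry <- list(
    dumpala = c(1L, 6L, 13L, 14L),
    dingle  = c(5L, 6L, 13L, 14L),
    acir    = c(1L, 2L, 7L, 8L, 13L, 14L),
    liu     = c(1L, 2L, 3L, 4L, 6L, 9L, 12L, 13L, 14L, 15L, 16L),
    all16   = 1:16
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(registry)) {
    stop("unknown peak model; valid names: ",
         paste(names(registry), collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, feature_ids = registry[[name]]),
            class = "peak_model")
}

#' Select a peak model's features from a full feature vector or matrix
#'
#' @param fv Named vector `f1` .. `f16` or a matrix with those columns.
#' @param model A `peak_model` or a model name.
#' @return The selected features, in the model's order.
#' @examples
#' fv <- stats::setNames(1:16, paste0("f", 1:16))
#' select_model_features(fv, "dumpala")  # 1 6 13 14
#' @export
select_model_features <- function(fv, model) {
  if (is.character(model)) model <- peak_model(model)
  cols <- paste0("f", model$feature_ids)
  if (is.matrix(fv)) fv[, cols, drop = FALSE] else fv[cols]
}
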
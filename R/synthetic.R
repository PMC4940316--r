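#' Specification for synthetic annotated EEG-like signals
#'
#' Describes a corpus of single-channel, already low-pass-filtered signals,
#' each 10 s at 256 Hz (2560 samples) carrying exactly one annotated
#' prominent peak riding on slow baseline drift plus noise — the structure of
#' an eye-movement EEG recording session. Defaults mirror that protocol:
#' 40 signals (20 per channel), peak widths 20-70 ms, and peak amplitudes of
#' 5-10 (arbitrary units). The default `noise_sd = 0.2` is calibrated to the
#' separability requirement that annotated peak amplitudes be at least five
#' times the amplitude of any noise-induced local maximum: across a
#' 2560-sample signal the largest excursion of the smoothed noise is about
#' five of its standard deviations, so candidates born of noise alone stay
#' below 1 amplitude unit while every annotated peak is at least 5.
#'
#' @param n_signals Number of signals (default 40).
#' @param n_samples Samples per signal (default 2560).
#' @param fs_hz Sampling rate in Hz (default 256).
#' @param peak_amplitude_range Range the peak amplitude is drawn from.
#' @param peak_width_range_ms Range of the full peak width (valley to
#'   valley) in milliseconds.
#' @param peak_asymmetry_range Range of the left/right half-width ratio.
#' @param baseline_drift_amplitude Amplitude of the slow sinusoidal drift.
#' @param noise_sd Standard deviation of the additive noise after smoothing.
#' @param noise_color `"white"` (smoothed white Gaussian, default) or
#'   `"pink"` (1/f) for harder scenarios.
#' @param seed Integer seed; every signal is deterministic given
#'   `(seed, index)`.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_signals = 40L, n_samples = 2560L, fs_hz = 256,
                       peak_amplitude_range = c(5, 10),
                       peak_width_range_ms = c(20, 70),
                       peak_asymmetry_range = c(0.5, 2),
                       baseline_drift_amplitude = 1,
                       noise_sd = 0.2,
                       noise_color = c("white", "pink"),
                       seed = 1L) {
  noise_color <- match.arg(noise_color)
  spec <- list(n_signals = as.integer(n_signals),
               n_samples = as.integer(n_samples),
               fs_hz = fs_hz,
               peak_amplitude_range = peak_amplitude_range,
               peak_width_range_ms = sort(peak_width_range_ms),
               peak_asymmetry_range = sort(peak_asymmetry_range),
               baseline_drift_amplitude = baseline_drift_amplitude,
               noise_sd = noise_sd,
               noise_color = noise_color,
               seed = as.integer(seed))
  max_w <- ceiling(max(spec$peak_width_range_ms) / 1000 * fs_hz)
  # peak must fit inside the signal with margin at least its own width
  if (3L * max_w + 2L >= spec$n_samples) {
    stop("infeasible spec: peak width ", max_w,
         " samples does not fit in ", spec$n_samples,
         " samples with margin >= width", call. = FALSE)
  }
  if (spec$n_signals < 1L || spec$noise_sd < 0 ||
      baseline_drift_amplitude < 0 || any(peak_amplitude_range <= 0)) {
    stop("invalid synth_spec parameters", call. = FALSE)
  }
  class(spec) <- "synth_spec"
  spec
}

#' Generate one annotated synthetic signal
#'
#' The signal is built as slow sinusoidal baseline drift plus smoothed
#' Gaussian noise, with one asymmetric peak superimposed at a uniformly drawn
#' admissible location. The peak is two truncated half-Gaussians of
#' independent widths meeting at a sharp apex, ending with a slight
#' undershoot at each edge of its support so the flanking valleys sit at the
#' drawn half-widths — on noiseless signals the realised valley-to-valley
#' width equals the width drawn from `peak_width_range_ms`. The apex index is
#' the single annotation.
#'
#' @param spec A [synth_spec].
#' @param index Signal index within the corpus (1-based); determinism is per
#'   `(seed, index)`.
#' @return An [eeg_signal] with one annotated peak and attribute `truth`
#'   recording the drawn peak parameters.
#' @export
generate_signal <- function(spec, index) {
  stopifnot(inherits(spec, "synth_spec"))
  L <- spec$n_samples
  fs <- spec$fs_hz
  with_rng_seed(spec$seed + as.integer(index), {
    w_ms <- stats::runif(1, spec$peak_width_range_ms[1], spec$peak_width_range_ms[2])
    w <- max(3L, as.integer(round(w_ms / 1000 * fs)))      # full width, samples
    r <- stats::runif(1, spec$peak_asymmetry_range[1], spec$peak_asymmetry_range[2])
    wl <- max(1L, as.integer(round(w * r / (1 + r))))
    wr <- max(1L, w - wl)
    amp <- stats::runif(1, spec$peak_amplitude_range[1], spec$peak_amplitude_range[2])
    margin <- wl + wr
    apex <- as.integer(floor(stats::runif(1, margin + 1, L - margin + 1)))

    t <- seq_len(L) - 1L
    drift <- if (spec$baseline_drift_amplitude > 0) {
      f_d <- stats::runif(1, 0.1, 0.5)
      phase <- stats::runif(1, 0, 2 * pi)
      spec$baseline_drift_amplitude * sin(2 * pi * f_d * t / fs + phase)
    } else rep(0, L)

    noise <- if (spec$noise_sd > 0) {
      z <- switch(spec$noise_color,
                  white = moving_average(stats::rnorm(L + 16L), 9L)[9:(L + 8L)],
                  pink = pink_noise(L))
      spec$noise_sd * z / stats::sd(z)
    } else rep(0, L)

    x <- drift + noise
    off <- (-wl):wr
    side_w <- ifelse(off < 0, wl, wr)
    u <- abs(off) / side_w
    # truncated half-Gaussians with a small undershoot at the support edges
    shape <- amp * (1.05 * exp(-(2.5 * u)^2 / 2) - 0.05)
    x[apex + off] <- x[apex + off] + shape

    sig <- eeg_signal(x, fs,
                      channel_id = if (index <= spec$n_signals / 2) "C3" else "C4",
                      true_peaks = apex)
    attr(sig, "truth") <- list(apex = apex, amplitude = amp,
                               width_samples = wl + wr,
                               half_widths = c(left = wl, right = wr))
    sig
  })
}

#' Generate a full synthetic corpus
#'
#' @param spec A [synth_spec].
#' @return List of [eeg_signal] in stable order, ready for
#'   [split_dataset()]; the first half carries channel label C3, the second
#'   C4.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  lapply(seq_len(spec$n_signals), function(i) generate_signal(spec, i))
}

#' Write a corpus to signal/annotation files plus a manifest
#'
#' Emits `signal_<i>.txt` and `signal_<i>_peaks.txt` per signal plus
#' `manifest.csv` with the drawn ground-truth parameters.
#'
#' @param signals List of [eeg_signal] (typically from [generate_dataset()]).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the manifest as a data.frame.
#' @export
write_dataset <- function(signals, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(signals), function(i) {
    sig <- signals[[i]]
    base <- file.path(dir, sprintf("signal_%03d", i))
    write_signal(sig, paste0(base, ".txt"), paste0(base, "_peaks.txt"))
    tr <- attr(sig, "truth")
    data.frame(index = i, file = basename(paste0(base, ".txt")),
               channel = sig$channel_id,
               apex = if (length(sig$true_peaks)) sig$true_peaks[1L] else NA,
               amplitude = if (is.null(tr)) NA else tr$amplitude,
               width_samples = if (is.null(tr)) NA else tr$width_samples)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# 1/f amplitude spectrum noise via FFT shaping
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)               # fold to two-sided frequencies
  shaped <- spec / sqrt(f)
  Re(stats::fft(shaped, inverse = TRUE)) / n
}
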
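#' Construct an annotated EEG signal
#'
#' An `eeg_signal` holds a single-channel discrete-time series together with
#' its sampling rate and the sample indices annotated as true peak locations.
#' Indices are 1-based throughout the package.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units).
#' @param sampling_rate_hz Positive sampling rate in Hz.
#' @param channel_id Channel label, e.g. `"C3"`.
#' @param true_peaks Integer vector of annotated peak sample indices,
#'   strictly increasing, each in `[1, length(samples)]`. May be empty.
#'
#' @return An object of class `eeg_signal` with fields `samples`,
#'   `sampling_rate_hz`, `channel_id` and `true_peaks`.
#' @examples
#' s <- eeg_signal(c(0, 1, 3, 1, 0), 256, true_peaks = 3L)
#' length(s$samples)
#' @export
eeg_signal <- function(samples, sampling_rate_hz, channel_id = "C3",
                       true_peaks = integer(0)) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L || anyNA(samples)) {
    stop("'samples' must be a non-empty numeric vector without NA", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("'sampling_rate_hz' must be a single positive number", call. = FALSE)
  }
  true_peaks <- as.integer(true_peaks)
  if (anyNA(true_peaks)) stop("'true_peaks' contains NA", call. = FALSE)
  if (length(true_peaks)) {
    if (any(true_peaks < 1L) || any(true_peaks > length(samples))) {
      stop("annotation index out of range [1, ", length(samples), "]",
           call. = FALSE)
    }
    if (any(diff(true_peaks) <= 0L)) {
      stop("'true_peaks' must be strictly increasing", call. = FALSE)
    }
  }
  structure(
    list(samples = samples,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         channel_id = as.character(channel_id),
         true_peaks = true_peaks),
    class = "eeg_signal"
  )
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf("<eeg_signal> channel %s: %d samples at %g Hz (%.3f s), %d annotated peak(s)\n",
              x$channel_id, length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz, length(x$true_peaks)))
  invisible(x)
}

#' Read a signal from a plain-text sample file
#'
#' Sample files hold one amplitude per row (a single CSV column is also
#' accepted); lines starting with `#` are comments. The optional annotation
#' file lists one integer peak index per row, 1-based.
#'
#' @param path Path to the sample file.
#' @param annotation_path Optional path to an annotation file. A missing or
#'   `NULL` path yields an empty `true_peaks`.
#' @param sampling_rate_hz Sampling rate in Hz (kept in the experiment
#'   configuration, not in the sample file).
#' @param channel_id Channel label.
#'
#' @return An [eeg_signal].
#' @seealso [write_signal()]
#' @export
read_signal <- function(path, annotation_path = NULL, sampling_rate_hz,
                        channel_id = "C3") {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  raw <- trimws(lines[keep])
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1L]]
    stop("non-numeric sample on line ", bad, " of '", path, "'", call. = FALSE)
  }
  peaks <- integer(0)
  if (!is.null(annotation_path) && file.exists(annotation_path)) {
    peaks <- read_annotations(annotation_path)
  }
  eeg_signal(vals, sampling_rate_hz, channel_id, sort(peaks))
}

read_annotations <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  raw <- trimws(lines[keep])
  if (!length(raw)) return(integer(0))
  vals <- suppressWarnings(as.integer(raw))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1L]]
    stop("non-integer annotation on line ", bad, " of '", path, "'",
         call. = FALSE)
  }
  vals
}

#' Write a signal (and its annotations) to plain-text files
#'
#' @param signal An [eeg_signal].
#' @param path Destination sample file, one amplitude per row.
#' @param annotation_path Optional destination for the annotation file;
#'   written only when the signal carries annotations.
#' @param digits Significant digits for the decimal representation; the
#'   default 17 round-trips doubles exactly.
#' @return Invisibly, `path`.
#' @export
write_signal <- function(signal, path, annotation_path = NULL, digits = 17L) {
  stopifnot(inherits(signal, "eeg_signal"))
  writeLines(c(sprintf("# channel %s, %g Hz, one amplitude per row",
                       signal$channel_id, signal$sampling_rate_hz),
               format(signal$samples, digits = digits, trim = TRUE,
                      scientific = FALSE)),
             path)
  if (!is.null(annotation_path) && length(signal$true_peaks)) {
    writeLines(c("# annotated peak sample indices, 1-based",
                 as.character(signal$true_peaks)),
               annotation_path)
  }
  invisible(path)
}

#' Split an ordered collection of signals into training and testing sets
#'
#' The first `ceiling(n * split_fraction)` signals (in the given order) form
#' the training set; the remainder form the test set. The split is across the
#' signal collection, not within signals: each recording holds a single
#' annotated peak, so a within-signal split would strand the peak in one half
#' (see the methods vignette).
#'
#' @param signals List of [eeg_signal] objects.
#' @param split_fraction Fraction assigned to training, in (0, 1). Default 0.5.
#' @return A list with elements `train` and `test`, each a list of signals.
#' @examples
#' sigs <- replicate(3, eeg_signal(c(0, 1, 0), 256), simplify = FALSE)
#' lengths(split_dataset(sigs))  # 2 train, 1 test
#' @export
split_dataset <- function(signals, split_fraction = 0.5) {
  if (!length(signals)) stop("empty dataset", call. = FALSE)
  if (!is.numeric(split_fraction) || split_fraction <= 0 || split_fraction >= 1) {
    stop("'split_fraction' must be in (0, 1)", call. = FALSE)
  }
  n <- length(signals)
  n_train <- as.integer(ceiling(n * split_fraction))
  list(train = signals[seq_len(n_train)],
       test = if (n_train < n) signals[(n_train + 1L):n] else list())
}

#' Read an experiment configuration file
#'
#' YAML key-value file carrying `sampling_rate_hz`, `split_fraction`, `model`,
#' ELM settings (`n_hidden`, `activation`), `seed`, `runs`, `tolerance` and
#' `mac_window`. Missing keys fall back to the defaults of
#' [experiment_config()].
#'
#' @param path Path to a YAML file.
#' @return An `experiment_config` list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(experiment_config, cfg)
}
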
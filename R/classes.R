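#' Construct a raw single-channel recording
#'
#' Container for a uniformly sampled physiological signal: an
#' electrohysterogram (EHG, in which the maternal ECG appears as
#' interference) or a maternal ECG, together with its sampling rate and
#' per-subject clinical metadata.
#'
#' @param samples Numeric vector of signal samples (arbitrary units).
#' @param fs Sampling rate in Hz (> 0).
#' @param modality `"EHG"` or `"ECG"`.
#' @param subject Optional named list of subject metadata: `id`, `age`
#'   (years), `bmi` (kg/m^2), `ga_recording` and `ga_delivery` (decimal
#'   weeks), `delivery_mode` (`"spontaneous"`, `"induced"`, `"cesarean"`),
#'   `dataset` (free-text cohort label).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, fs, modality = c("EHG", "ECG"),
                          subject = list()) {
  modality <- match.arg(modality)
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop2("`fs` must be a single positive number (Hz)")
  }
  if (!all(is.finite(samples))) stop2("`samples` must be finite")
  ga_r <- subject$ga_recording
  ga_d <- subject$ga_delivery
  if (!is.null(ga_r) && !is.null(ga_d) && is.finite(ga_r) && is.finite(ga_d) &&
      ga_d < ga_r) {
    stop2("subject metadata invalid: ga_delivery < ga_recording")
  }
  structure(
    list(samples = samples, fs = fs, modality = modality, subject = subject),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s, %d samples @ %g Hz (%.1f s)\n",
              x$modality, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  if (!is.null(x$subject$id)) cat("  subject:", x$subject$id, "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `raw_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) length(rec$samples) / rec$fs

#' Crop a recording to a time window
#' @param rec A `raw_recording`.
#' @param start,duration Window start and length in seconds.
#' @return A `raw_recording` holding the window.
#' @export
crop_recording <- function(rec, start, duration) {
  i0 <- floor(start * rec$fs) + 1L
  i1 <- min(length(rec$samples), floor((start + duration) * rec$fs))
  if (i0 >= i1) stop2("crop window outside recording")
  raw_recording(rec$samples[i0:i1], rec$fs, rec$modality, rec$subject)
}

#' Construct a detected R-peak series
#'
#' @param indices Integer sample positions of detected R peaks (1-based,
#'   strictly increasing).
#' @param fs Sampling rate in Hz.
#' @return An object of class `rpeak_series` with elements `indices`,
#'   `times` (seconds) and `fs`.
#' @export
rpeak_series <- function(indices, fs) {
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE)) {
    stop2("peak indices must be strictly increasing")
  }
  structure(list(indices = indices, times = (indices - 1L) / fs, fs = fs),
            class = "rpeak_series")
}

#' Construct an RR-interval series
#'
#' Beat-to-beat intervals in milliseconds with per-interval annotations.
#' Interval `i` spans `beat_times[i]` to `beat_times[i + 1]`.
#'
#' @param intervals RR intervals in ms (all > 0).
#' @param beat_times Beat times in seconds, length `length(intervals) + 1`.
#' @param labels Per-interval labels among `"normal"`, `"ectopic"`,
#'   `"corrected"`; defaults to all `"normal"`.
#' @return An object of class `rri_series`.
#' @export
rri_series <- function(intervals, beat_times, labels = NULL) {
  intervals <- as.numeric(intervals)
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) != length(intervals) + 1L) {
    stop2("need length(beat_times) == length(intervals) + 1")
  }
  if (any(intervals <= 0)) stop2("all RR intervals must be positive")
  if (is.unsorted(beat_times, strictly = TRUE)) {
    stop2("beat times must be strictly increasing")
  }
  labels <- labels %||% rep("normal", length(intervals))
  if (!all(labels %in% c("normal", "ectopic", "corrected"))) {
    stop2("labels must be 'normal', 'ectopic' or 'corrected'")
  }
  structure(list(intervals = intervals, beat_times = beat_times,
                 labels = labels),
            class = "rri_series")
}

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf("<rri_series> %d intervals, mean RR %.1f ms, %d corrected\n",
              length(x$intervals), mean(x$intervals),
              sum(x$labels != "normal")))
  invisible(x)
}

#' @export
length.rri_series <- function(x) length(x$intervals)
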
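#' Zero-phase high-pass filter
#'
#' Removes baseline drift and low-frequency uterine activity ahead of R-peak
#' detection. A Butterworth design applied forward--backward
#' ([signal::filtfilt()]), so there is no group delay and peak positions are
#' not shifted. Defaults: 5 Hz cutoff for EHG (uterine EMG and wander lie
#' well below, QRS energy at 10--40 Hz), 0.5 Hz for clean ECG.
#'
#' @param rec A [raw_recording()].
#' @param cutoff Cutoff frequency in Hz; defaults by modality (5 for EHG,
#'   0.5 for ECG). Must lie in (0, fs/2).
#' @param order Butterworth order (default 4).
#' @return A filtered [raw_recording()] of the same length; any `"truth"`
#'   attribute is carried through.
#' @export
highpass_filter <- function(rec, cutoff = NULL, order = 4L) {
  stopifnot(inherits(rec, "raw_recording"))
  cutoff <- cutoff %||% if (rec$modality == "EHG") 5 else 0.5
  if (cutoff <= 0 || cutoff >= rec$fs / 2) {
    stop2("cutoff must lie strictly between 0 and the Nyquist frequency (",
          rec$fs / 2, " Hz)")
  }
  bf <- signal::butter(order, cutoff / (rec$fs / 2), type = "high")
  y <- signal::filtfilt(bf, rec$samples)
  out <- raw_recording(y, rec$fs, rec$modality, rec$subject)
  attr(out, "truth") <- attr(rec, "truth")
  out
}

#' Normalize a recording to unit maximum amplitude
#'
#' Scales the signal by its maximum absolute value so that peak-detection
#' thresholds can be expressed as fractions of the normalized maximum.
#'
#' @param rec A [raw_recording()].
#' @return A [raw_recording()] with `max(abs(samples)) == 1`.
#' @export
normalize_amplitude <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  m <- max(abs(rec$samples))
  if (m == 0) stop2("cannot normalize an all-zero signal")
  out <- raw_recording(rec$samples / m, rec$fs, rec$modality, rec$subject)
  attr(out, "truth") <- attr(rec, "truth")
  out
}
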
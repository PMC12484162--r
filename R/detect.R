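#' Detect R peaks in a filtered, normalized recording
#'
#' Finds local maxima exceeding a threshold expressed as a fraction of the
#' normalized maximum, then enforces a refractory period: when two
#' candidates fall within the refractory window the larger one is kept.
#'
#' @param rec A filtered and amplitude-normalized [raw_recording()].
#' @param min_height Detection threshold as a fraction of the normalized
#'   maximum (default 0.4).
#' @param refractory Minimum separation between retained peaks in ms
#'   (default 250, i.e. a 240 bpm ceiling).
#' @return An [rpeak_series()].
#' @export
detect_rpeaks <- function(rec, min_height = 0.4, refractory = 250) {
  stopifnot(inherits(rec, "raw_recording"))
  x <- rec$samples
  n <- length(x)
  if (n < 3L) stop2("no peaks detected: signal too short")
  i <- 2:(n - 1L)
  cand <- i[x[i] > x[i - 1L] & x[i] >= x[i + 1L] & x[i] >= min_height]
  if (!length(cand)) {
    stop2("no peaks detected (threshold ", min_height,
          ", signal max ", signif(max(x), 3), ")")
  }
  refr_samp <- refractory / 1000 * rec$fs
  # greedy by descending height: a candidate survives only if no taller
  # already-kept peak lies within the refractory window
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || min(abs(kept - p)) >= refr_samp) {
      kept <- c(kept, p)
    }
  }
  rpeak_series(sort(kept), rec$fs)
}

#' Convert detected R peaks to an RR-interval series
#'
#' @param peaks An [rpeak_series()] with at least two peaks.
#' @return An [rri_series()] with intervals in ms (successive peak-time
#'   differences times 1000) and all labels `"normal"`.
#' @export
peaks_to_rri <- function(peaks) {
  stopifnot(inherits(peaks, "rpeak_series"))
  if (length(peaks$times) < 2L) stop2("need at least 2 peaks to form intervals")
  rri_series(diff(peaks$times) * 1000, peaks$times)
}

#' Select a usable 5-minute segment from a recording
#'
#' Evaluates consecutive non-overlapping 300 s windows from the start of the
#' record and returns the first in which R-peak extraction succeeds with an
#' acceptably small corrected-beat fraction and a physiologically plausible
#' beat count. The beginning of the record is thus the favored choice, with
#' later windows used only when the first is too noisy. If no window
#' qualifies the record is excluded with reason "poorly detectable R peaks".
#'
#' @param rec A raw (unfiltered) [raw_recording()] of at least 300 s.
#' @param quality_threshold Maximum tolerated fraction of flagged (to be
#'   corrected) intervals in the window (default 0.05).
#' @param duration Window length in seconds; 300 s is the minimum
#'   recommended length for frequency-domain HRV and is the supported value.
#' @param min_beats Minimum plausible beat count per window (default 150,
#'   i.e. mean RR <= 2 s).
#' @param config Pipeline parameters used for the per-window trial
#'   extraction (see [pipeline_config()]).
#' @return A list of class `segment_selection`: `start` (s), `duration`,
#'   `quality` (list with `fraction_corrected`, `n_beats`).
#' @export
select_segment <- function(rec, quality_threshold = 0.05, duration = 300,
                           min_beats = 150L, config = pipeline_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  total <- recording_duration(rec)
  if (total < duration) {
    stop2("record shorter than the ", duration, " s minimum for HRV analysis")
  }
  starts <- seq(0, total - duration, by = duration)
  for (s in starts) {
    q <- tryCatch({
      win <- crop_recording(rec, s, duration)
      win <- normalize_amplitude(highpass_filter(
        win, cutoff = segment_cutoff(config, rec$modality),
        order = config$filter$order))
      peaks <- detect_rpeaks(win, config$detection$min_height,
                             config$detection$refractory)
      rri <- peaks_to_rri(peaks)
      flags <- suppressWarnings(
        flag_ectopics(rri, config$ectopic$dev_threshold,
                      config$ectopic$bounds))
      list(fraction_corrected = mean(flags), n_beats = length(peaks$indices))
    }, error = function(e) NULL)
    if (!is.null(q) && q$n_beats >= min_beats &&
        q$fraction_corrected <= quality_threshold) {
      return(structure(list(start = s, duration = duration, quality = q),
                       class = "segment_selection"))
    }
  }
  stop2("record excluded: poorly detectable R peaks ",
        "(no usable ", duration, " s window)")
}

segment_cutoff <- function(config, modality) {
  if (modality == "EHG") config$filter$cutoff_ehg else config$filter$cutoff_ecg
}

#' Score detected peaks against ground truth
#'
#' Greedy one-to-one matching of detected to true beats within a tolerance.
#' Both lists are scanned in time order; each true beat is matched to the
#' nearest still-unmatched detection within `tol`.
#'
#' @param detected An [rpeak_series()], or a numeric vector of times (s).
#' @param truth Ground truth from a synthesizer (list with `beat_times`), or
#'   a numeric vector of true beat times (s).
#' @param tol Matching tolerance in ms (default 10).
#' @return A list: `sensitivity` (matched / true), `ppv`
#'   (matched / detected), `n_matched`, `n_true`, `n_detected`.
#' @export
evaluate_detection <- function(detected, truth, tol = 10) {
  det <- if (inherits(detected, "rpeak_series")) detected$times else detected
  tru <- if (is.list(truth)) truth$beat_times else truth
  tol_s <- tol / 1000
  used <- logical(length(det))
  matched <- 0L
  j <- 1L
  for (t in tru) {
    while (j <= length(det) && det[j] < t - tol_s) j <- j + 1L
    # candidates within tolerance, nearest first
    k <- j
    best <- 0L
    best_d <- Inf
    while (k <= length(det) && det[k] <= t + tol_s) {
      if (!used[k] && abs(det[k] - t) < best_d) {
        best <- k
        best_d <- abs(det[k] - t)
      }
      k <- k + 1L
    }
    if (best > 0L) {
      used[best] <- TRUE
      matched <- matched + 1L
    }
  }
  list(sensitivity = if (length(tru)) matched / length(tru) else NA_real_,
       ppv = if (length(det)) matched / length(det) else NA_real_,
       n_matched = matched, n_true = length(tru), n_detected = length(det))
}
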
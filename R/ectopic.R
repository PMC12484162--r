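#' Flag ectopic (artifactual) RR intervals
#'
#' Automated surrogate for manual ectopic-beat review: an interval is
#' flagged when it deviates by more than `dev_threshold` from the running
#' median of the (up to) 5 preceding unflagged intervals, and intervals
#' outside the physiologic screen are always flagged. A premature beat thus
#' flags both the short interval and its compensatory pause.
#'
#' @param rri An [rri_series()] with at least 6 intervals (shorter series
#'   return no flags, with a warning).
#' @param dev_threshold Relative deviation from the running median that
#'   triggers a flag (default 0.2, i.e. 20%).
#' @param bounds Physiologic RR bounds in ms (default `c(250, 2000)`);
#'   intervals outside are always flagged.
#' @return Logical vector, one flag per interval.
#' @export
flag_ectopics <- function(rri, dev_threshold = 0.2, bounds = c(250, 2000)) {
  stopifnot(inherits(rri, "rri_series"))
  x <- rri$intervals
  n <- length(x)
  flags <- logical(n)
  if (n < 6L) {
    warning("fewer than 6 intervals: ectopic screening skipped")
    return(flags)
  }
  for (i in seq_len(n)) {
    if (x[i] < bounds[1] || x[i] > bounds[2]) {
      flags[i] <- TRUE
      next
    }
    prev <- which(!flags[seq_len(i - 1L)])
    if (length(prev)) {
      ref <- stats::median(x[utils::tail(prev, 5L)])
      if (abs(x[i] - ref) / ref > dev_threshold) flags[i] <- TRUE
    }
  }
  flags
}

#' Correct flagged intervals by duration-preserving run means
#'
#' Each maximal run of consecutive flagged intervals is replaced by equal
#' intervals, each the mean of the run (run total duration divided by run
#' length), so total series duration is preserved exactly. This restores a
#' premature-beat/compensatory-pause pair to two near-normal intervals.
#' Unflagged intervals are untouched; corrected intervals are relabelled.
#' Applying the correction twice with the same flags is a no-op.
#'
#' @param rri An [rri_series()].
#' @param flags Logical vector aligned with `rri$intervals` (e.g. from
#'   [flag_ectopics()]).
#' @return A corrected [rri_series()].
#' @export
correct_ectopics <- function(rri, flags) {
  stopifnot(inherits(rri, "rri_series"))
  if (length(flags) != length(rri$intervals)) {
    stop2("flags must align with intervals")
  }
  if (all(flags)) stop2("every interval flagged: series unusable")
  if (!any(flags)) return(rri)
  x <- rri$intervals
  labels <- rri$labels
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    x[idx] <- sum(rri$intervals[idx]) / length(idx)
    labels[idx] <- "corrected"
  }
  bt <- rri$beat_times[1L] + c(0, cumsum(x)) / 1000
  rri_series(x, bt, labels)
}
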
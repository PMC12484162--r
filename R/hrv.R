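#' Standard short-term HRV frequency bands
#'
#' Very-low, low and high frequency band edges in Hz used throughout the
#' package: VLF 0.0033--0.04, LF 0.04--0.15, HF 0.15--0.4 Hz.
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
hrv_bands <- function() {
  list(vlf = c(0.0033, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.4))
}

#' Time-domain HRV indices
#'
#' Mean RR, SDNN (sample standard deviation of the intervals, n-1
#' denominator) and RMSSD (root mean square of successive interval
#' differences), all in ms.
#'
#' @param rri An [rri_series()] with at least 2 intervals.
#' @return Named list: `mean_rr`, `sdnn`, `rmssd`.
#' @export
time_domain <- function(rri) {
  x <- if (inherits(rri, "rri_series")) rri$intervals else as.numeric(rri)
  if (length(x) < 2L) stop2("need at least 2 intervals")
  list(mean_rr = mean(x),
       sdnn = stats::sd(x),
       rmssd = sqrt(mean(diff(x)^2)))
}

#' Resample an RR series onto a uniform grid (tachogram)
#'
#' Cubic-spline interpolation of (beat time, interval) pairs onto a uniform
#' grid, the evenly sampled series required for band-power analysis. Each
#' interval is anchored at the time of the beat that ends it.
#'
#' @param rri An [rri_series()] with at least 4 beats.
#' @param fs_interp Interpolation rate in Hz (default 4, comfortably above
#'   twice the 0.4 Hz upper analysis band edge).
#' @return A list of class `tachogram`: `values` (ms), `fs_interp`, `t0`
#'   (grid start, s).
#' @export
resample_tachogram <- function(rri, fs_interp = 4) {
  stopifnot(inherits(rri, "rri_series"))
  if (length(rri$intervals) < 4L) stop2("need at least 4 beats to resample")
  tx <- rri$beat_times[-1L]
  f <- stats::splinefun(tx, rri$intervals, method = "fmm")
  grid <- tx[1L] + seq(0, floor((tx[length(tx)] - tx[1L]) * fs_interp)) /
    fs_interp
  structure(list(values = f(grid), fs_interp = fs_interp, t0 = grid[1L]),
            class = "tachogram")
}

#' Power spectral density of a tachogram
#'
#' Averaged modified periodogram (Welch's method): the linearly detrended
#' tachogram is split into tapered (Hann) segments with 50% overlap, each
#' segment's one-sided periodogram is computed, and the results are
#' averaged. Scaling is such that the integral of the density over frequency
#' recovers the series variance (up to taper leakage, within ~10%).
#'
#' @param tach A `tachogram` from [resample_tachogram()].
#' @param window_s Segment length in seconds (default 150; two segments plus
#'   an overlapped third for a standard 300 s record).
#' @param overlap Fractional segment overlap (default 0.5).
#' @param detrend Remove a linear trend first (default `TRUE`); suppresses
#'   within-segment drift that would otherwise leak into VLF.
#' @return A list of class `spectral_estimate`: `freqs` (Hz),
#'   `power_density` (ms^2/Hz), `resolution` (Hz), `method_params`.
#' @export
estimate_psd <- function(tach, window_s = 150, overlap = 0.5,
                         detrend = TRUE) {
  stopifnot(inherits(tach, "tachogram"))
  x <- tach$values
  fs <- tach$fs_interp
  n <- length(x)
  L <- round(window_s * fs)
  if (L > n) stop2("tachogram shorter than one analysis window (",
                   window_s, " s)")
  if (detrend) {
    tt <- seq_len(n)
    x <- stats::residuals(stats::lm.fit(cbind(1, tt), x))
  } else {
    x <- x - mean(x)
  }
  w <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1)))   # Hann
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf)]
    acc <- acc + Mod(X)^2
  }
  # one-sided density: double interior bins; normalize by fs * sum(w^2)
  p <- acc / length(starts) / (fs * sum(w^2))
  p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
  structure(list(
    freqs = (seq_len(nf) - 1L) * fs / L,
    power_density = p,
    resolution = fs / L,
    method_params = list(window_s = window_s, overlap = overlap,
                         taper = "hann", detrend = detrend,
                         n_segments = length(starts), fs_interp = fs)
  ), class = "spectral_estimate")
}

# Trapezoidal band integral with linear interpolation at the band edges.
band_integral <- function(freqs, density, band) {
  lo <- max(band[1], freqs[1])
  hi <- min(band[2], freqs[length(freqs)])
  if (hi <= lo) return(0)
  inside <- freqs > lo & freqs < hi
  fg <- c(lo, freqs[inside], hi)
  pg <- stats::approx(freqs, density, xout = fg)$y
  trapz(fg, pg)
}

#' Band powers and LF/HF ratio from a spectral estimate
#'
#' Integrates the density over the standard VLF, LF and HF bands
#' (trapezoidal rule with edge interpolation) and reports each band power as
#' its natural log of the raw power in ms^2, plus the ratio of raw LF to raw
#' HF power. VLF from a single 5-minute segment covers roughly one cycle of
#' its lower edge and is reported with a low-reliability flag.
#'
#' @param psd A `spectral_estimate` from [estimate_psd()].
#' @return Named list: `vlf_ln`, `lf_ln`, `hf_ln` (ln ms^2), `lf_hf`
#'   (raw-power ratio), plus attributes `bands` (the edges used) and
#'   `vlf_low_reliability`.
#' @export
band_powers <- function(psd) {
  stopifnot(inherits(psd, "spectral_estimate"))
  bands <- hrv_bands()
  if (psd$freqs[length(psd$freqs)] < bands$hf[2]) {
    stop2("spectral estimate does not cover the HF band up to 0.4 Hz")
  }
  p <- vapply(bands, function(b)
    band_integral(psd$freqs, psd$power_density, b), numeric(1))
  if (p[["hf"]] <= 0) stop2("zero HF power: LF/HF ratio undefined")
  structure(
    list(vlf_ln = log(p[["vlf"]]), lf_ln = log(p[["lf"]]),
         hf_ln = log(p[["hf"]]), lf_hf = p[["lf"]] / p[["hf"]]),
    bands = bands, vlf_low_reliability = TRUE, raw_powers = p
  )
}

#' Compute all HRV indices for a corrected 5-minute RR series
#'
#' Orchestrates [time_domain()], [resample_tachogram()], [estimate_psd()]
#' and [band_powers()] into one record, carrying the spectral method
#' parameters for provenance.
#'
#' @param rri A corrected [rri_series()] spanning a 5-minute segment.
#' @param fs_interp Tachogram interpolation rate (Hz).
#' @param window_s,overlap,detrend Passed to [estimate_psd()].
#' @return A list of class `hrv_metrics`: `mean_rr`, `sdnn`, `rmssd` (ms),
#'   `vlf_ln`, `lf_ln`, `hf_ln` (ln ms^2), `lf_hf`, plus attribute
#'   `method_params`.
#' @export
compute_hrv <- function(rri, fs_interp = 4, window_s = 150, overlap = 0.5,
                        detrend = TRUE) {
  td <- time_domain(rri)
  tach <- resample_tachogram(rri, fs_interp)
  psd <- estimate_psd(tach, window_s, overlap, detrend)
  bp <- band_powers(psd)
  structure(
    list(mean_rr = td$mean_rr, sdnn = td$sdnn, rmssd = td$rmssd,
         vlf_ln = bp$vlf_ln, lf_ln = bp$lf_ln, hf_ln = bp$hf_ln,
         lf_hf = bp$lf_hf),
    method_params = psd$method_params,
    class = "hrv_metrics"
  )
}

#' @export
print.hrv_metrics <- function(x, ...) {
  cat(sprintf(
    "<hrv_metrics> RR %.1f ms | SDNN %.1f ms | RMSSD %.1f ms | VLF %.2f | LF %.2f | HF %.2f (Ln ms^2) | LF/HF %.2f\n",
    x$mean_rr, x$sdnn, x$rmssd, x$vlf_ln, x$lf_ln, x$hf_ln, x$lf_hf))
  invisible(x)
}
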
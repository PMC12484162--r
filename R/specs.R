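#' Specification of a simulated tachogram
#'
#' Parameters of the integral pulse frequency modulation (IPFM) beat
#' generator: a mean interbeat interval plus a set of sinusoidal rate
#' modulations placed in the standard short-term HRV bands.
#'
#' @param mean_rr Mean RR interval in ms (> 0).
#' @param modulations List of `c(freq, rel_amplitude)` pairs (or a 2-column
#'   matrix); frequencies in (0, 0.5] Hz, relative amplitudes in [0, 1) with
#'   sum < 1 so the instantaneous rate stays positive.
#' @param duration Length of the simulated record in seconds.
#' @param seed Integer seed for the modulation phases.
#' @return An object of class `tachogram_spec`.
#' @export
tachogram_spec <- function(mean_rr = 800, modulations = list(),
                           duration = 300, seed = 1L) {
  if (!is.numeric(mean_rr) || mean_rr <= 0) stop2("mean_rr must be > 0")
  if (!is.numeric(duration) || duration <= 0) {
    stop2("duration must be a positive number of seconds")
  }
  if (is.matrix(modulations)) {
    modulations <- lapply(seq_len(nrow(modulations)),
                          function(i) modulations[i, ])
  }
  for (m in modulations) {
    if (length(m) != 2L) stop2("each modulation is c(freq, rel_amplitude)")
    if (m[1] <= 0 || m[1] > 0.5) stop2("modulation freq must be in (0, 0.5] Hz")
    if (m[2] < 0 || m[2] >= 1) stop2("rel_amplitude must be in [0, 1)")
  }
  amps <- vapply(modulations, `[`, numeric(1), 2L)
  if (length(amps) && sum(amps) >= 1) {
    stop2("sum of modulation amplitudes must be < 1 ",
          "(instantaneous rate must stay positive)")
  }
  structure(list(mean_rr = mean_rr, modulations = modulations,
                 duration = duration, seed = as.integer(seed)),
            class = "tachogram_spec")
}

#' Specification of a synthetic electrohysterogram
#'
#' Describes the components layered onto a QRS pulse train to emulate an
#' abdominal EHG recording: uterine contraction bursts (band-limited noise
#' under raised-cosine envelopes), slow sinusoidal baseline wander, and
#' broadband instrument noise.
#'
#' @param fs Sampling rate in Hz (>= 100).
#' @param ecg_gain Multiplier on the unit-amplitude QRS train. The default 4
#'   places the cardiac component roughly 12 dB above the background, i.e. a
#'   record with clearly visible R peaks.
#' @param contraction_rate Expected contraction bursts per 5 minutes.
#' @param contraction_band Passband (Hz) of the uterine EMG noise; upper edge
#'   must be < 5 Hz.
#' @param contraction_amp Standard deviation of a burst at envelope peak.
#' @param wander_freq,wander_amp Baseline wander frequency (< 0.1 Hz) and
#'   amplitude.
#' @param noise_sd Standard deviation of added white noise.
#' @param qrs_width QRS width (full width at half maximum) in ms.
#' @param seed Integer seed.
#' @return An object of class `ehg_spec`.
#' @export
ehg_spec <- function(fs = 200, ecg_gain = 4, contraction_rate = 2,
                     contraction_band = c(0.1, 3), contraction_amp = 0.2,
                     wander_freq = 0.02, wander_amp = 0.15,
                     noise_sd = 0.02, qrs_width = 20, seed = 1L) {
  if (fs < 100) stop2("fs must be >= 100 Hz")
  if (contraction_band[2] >= 5) stop2("contraction band upper edge must be < 5 Hz")
  if (contraction_band[1] <= 0 || contraction_band[1] >= contraction_band[2]) {
    stop2("contraction_band must be an increasing positive pair")
  }
  if (wander_freq >= 0.1) stop2("wander_freq must be < 0.1 Hz")
  structure(list(fs = fs, ecg_gain = ecg_gain,
                 contraction_rate = contraction_rate,
                 contraction_band = contraction_band,
                 contraction_amp = contraction_amp,
                 wander_freq = wander_freq, wander_amp = wander_amp,
                 noise_sd = noise_sd, qrs_width = qrs_width,
                 seed = as.integer(seed)),
            class = "ehg_spec")
}

#' Specification of a synthetic cohort
#'
#' Defines a cohort of pregnant subjects with time to delivery (TTD) drawn
#' uniformly on `ttd_range` and per-subject true HRV parameters tied to TTD
#' through planted Spearman correlations.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param ttd_range Range (weeks) for time to delivery; default `c(0, 9.3)`,
#'   the span observed in late-third-trimester cohorts of this kind.
#' @param effect_map Named numeric vector of planted Spearman correlations
#'   between a metric and TTD; supported names: `"rmssd"`, `"lf_hf"`.
#'   An empty map plants no effect (null cohort).
#' @param delivery_mode_probs Probabilities over
#'   `c(spontaneous, induced, cesarean)`; must sum to 1.
#' @param mean_rr_mean,mean_rr_sd Across-subject distribution of the mean RR
#'   interval (ms).
#' @param fs Sampling rate for synthesized recordings (Hz).
#' @param duration Recording duration per subject (s); >= 310 so a full
#'   5-minute analysis segment is always available.
#' @param noise_sd White-noise level of the synthesized ECGs.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, ttd_range = c(0, 9.3),
                        effect_map = c(lf_hf = 0.55, rmssd = -0.50),
                        delivery_mode_probs = c(spontaneous = 1,
                                                induced = 0, cesarean = 0),
                        mean_rr_mean = 780, mean_rr_sd = 40,
                        fs = 200, duration = 310, noise_sd = 0.02,
                        seed = 1L) {
  if (n_subjects < 3) stop2("n_subjects must be >= 3")
  if (diff(ttd_range) < 0) stop2("ttd_range must be non-decreasing")
  if (abs(sum(delivery_mode_probs) - 1) > 1e-8) {
    stop2("delivery_mode_probs must sum to 1")
  }
  if (length(effect_map)) {
    if (is.null(names(effect_map)) ||
        !all(names(effect_map) %in% c("rmssd", "lf_hf"))) {
      stop2("effect_map names must be among 'rmssd', 'lf_hf'")
    }
    if (any(abs(effect_map) >= 1)) stop2("planted correlations must be in (-1, 1)")
  }
  structure(list(n_subjects = as.integer(n_subjects), ttd_range = ttd_range,
                 effect_map = effect_map,
                 delivery_mode_probs = delivery_mode_probs,
                 mean_rr_mean = mean_rr_mean, mean_rr_sd = mean_rr_sd,
                 fs = fs, duration = duration, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}
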
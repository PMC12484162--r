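# Gaussian QRS pulse train. Centers are snapped to the nearest sample so the
# sampled maximum equals `amplitude` exactly; the snap error (<= half a
# sample) is far below the 10 ms matching tolerance used in validation.
qrs_train <- function(beat_times, fs, duration, qrs_width = 20,
                      amplitude = 1) {
  n <- ceiling(duration * fs)
  x <- numeric(n)
  sd_samp <- (qrs_width / 1000) / 2.355 * fs   # FWHM -> sd, in samples
  half <- ceiling(5 * sd_samp)
  centers <- round(beat_times * fs) + 1L
  for (c0 in centers) {
    i <- max(1L, c0 - half):min(n, c0 + half)
    x[i] <- x[i] + amplitude * exp(-((i - c0)^2) / (2 * sd_samp^2))
  }
  list(signal = x, peak_indices = centers[centers >= 1L & centers <= n])
}

#' Synthesize a maternal ECG recording from known beat times
#'
#' Each beat is rendered as a single Gaussian pulse (full P-QRS-T morphology
#' is unnecessary for R-peak logic), plus optional white noise. The sample
#' index of every true peak is retained as ground truth for detector
#' validation.
#'
#' @param beat_times Strictly increasing beat times in seconds (e.g. from
#'   [generate_rri_ipfm()]).
#' @param fs Sampling rate in Hz; must satisfy `fs >= 4 * 1000 / qrs_width`.
#' @param qrs_width QRS width (FWHM) in ms.
#' @param amplitude Peak amplitude of the noise-free pulses.
#' @param noise_sd Standard deviation of added white noise.
#' @param seed Integer seed for the noise.
#' @param subject Optional subject metadata list (see [raw_recording()]).
#' @return A [raw_recording()] (modality `"ECG"`) with attribute `"truth"`:
#'   `peak_indices`, `beat_times`.
#' @export
synthesize_ecg <- function(beat_times, fs = 1000, qrs_width = 20,
                           amplitude = 1, noise_sd = 0, seed = 1L,
                           subject = list()) {
  if (is.unsorted(beat_times, strictly = TRUE)) {
    stop2("beat_times must be strictly increasing")
  }
  if (fs < 4 * 1000 / qrs_width) {
    stop2("fs too low to resolve the QRS width (need fs >= 4 * 1/width)")
  }
  duration <- max(beat_times) + 0.5
  tr <- qrs_train(beat_times, fs, duration, qrs_width, amplitude)
  x <- tr$signal
  if (noise_sd > 0) {
    x <- x + with_seed(seed, stats::rnorm(length(x), 0, noise_sd))
  }
  rec <- raw_recording(x, fs, "ECG", subject)
  attr(rec, "truth") <- list(peak_indices = tr$peak_indices,
                             beat_times = beat_times)
  rec
}

#' Synthesize an electrohysterogram with embedded maternal ECG
#'
#' Emulates an abdominal EHG record in which the maternal ECG appears as
#' interference riding on uterine activity: a scaled QRS train, uterine
#' contraction bursts (band-limited noise under raised-cosine envelopes of
#' 30--60 s), slow sinusoidal baseline wander, and broadband noise. The
#' achieved ECG-to-background power ratio is reported in the ground truth so
#' detector robustness can be conditioned on it.
#'
#' @param beat_times Strictly increasing beat times in seconds.
#' @param spec An [ehg_spec()].
#' @param subject Optional subject metadata list.
#' @return A [raw_recording()] (modality `"EHG"`) with attribute `"truth"`:
#'   `peak_indices`, `beat_times`, `ecg_to_background_db`, component powers.
#' @export
synthesize_ehg <- function(beat_times, spec = ehg_spec(), subject = list()) {
  stopifnot(inherits(spec, "ehg_spec"))
  if (is.unsorted(beat_times, strictly = TRUE)) {
    stop2("beat_times must be strictly increasing")
  }
  fs <- spec$fs
  duration <- max(beat_times) + 0.5
  n <- ceiling(duration * fs)
  tt <- (seq_len(n) - 1L) / fs

  tr <- qrs_train(beat_times, fs, duration, spec$qrs_width, 1)
  ecg <- spec$ecg_gain * tr$signal

  background <- with_seed(spec$seed, {
    bg <- numeric(n)
    # contraction bursts: band-limited noise under raised-cosine envelopes
    n_events <- round(spec$contraction_rate * duration / 300)
    if (n_events > 0 && spec$contraction_amp > 0) {
      bp <- signal::butter(2, spec$contraction_band / (fs / 2), "pass")
      raw <- signal::filtfilt(bp, stats::rnorm(n))
      raw <- raw / stats::sd(raw)
      centers <- stats::runif(n_events, 0.1, 0.9) * duration
      for (c0 in centers) {
        dur_ev <- stats::runif(1, 30, 60)
        i0 <- max(1L, floor((c0 - dur_ev / 2) * fs))
        i1 <- min(n, ceiling((c0 + dur_ev / 2) * fs))
        env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = i1 - i0 + 1L)))
        bg[i0:i1] <- bg[i0:i1] + spec$contraction_amp * env * raw[i0:i1]
      }
    }
    if (spec$wander_amp > 0) {
      bg <- bg + spec$wander_amp *
        sin(2 * pi * spec$wander_freq * tt + stats::runif(1, 0, 2 * pi))
    }
    if (spec$noise_sd > 0) bg <- bg + stats::rnorm(n, 0, spec$noise_sd)
    bg
  })

  p_ecg <- mean(ecg^2)
  p_bg <- mean(background^2)
  rec <- raw_recording(ecg + background, fs, "EHG", subject)
  attr(rec, "truth") <- list(
    peak_indices = tr$peak_indices,
    beat_times = beat_times,
    ecg_power = p_ecg,
    background_power = p_bg,
    ecg_to_background_db = if (p_bg > 0) 10 * log10(p_ecg / p_bg) else Inf
  )
  rec
}

# Map a planted Spearman rho to the Pearson correlation of the Gaussian
# copula that induces it (Pearson 1907 relation); monotone marginal
# transforms then preserve the planted rank correlation.
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Generate a synthetic cohort with planted HRV-outcome correlations
#'
#' Draws per-subject time to delivery (TTD) uniformly on `ttd_range`, ties
#' true HRV parameters (RMSSD, LF/HF ratio) to TTD through a Gaussian copula
#' so the planted Spearman correlations of `effect_map` hold in expectation,
#' and (optionally) synthesizes a full ECG recording per subject whose
#' IPFM tone amplitudes realize those parameters. GA at delivery is drawn
#' around 40 weeks and GA at recording set so that
#' `ga_delivery - ga_recording = ttd` exactly.
#'
#' Marginals follow late-pregnancy cohorts of this kind: RMSSD centered on
#' 25 ms, LF/HF log-normal around 0.5, mean RR near 780 ms. Subject
#' dispersion is the copula's residual noise; the achieved sample Spearman
#' correlations of the true parameters against TTD are documented in the
#' `planted` attribute of the truth table.
#'
#' @param spec A [cohort_spec()].
#' @param synthesize If `TRUE` (default) synthesize one ECG recording per
#'   subject; if `FALSE` return only the ground-truth table (used for
#'   large-replicate statistical calibration).
#' @return A list with `recordings` (list of [raw_recording()], or `NULL`)
#'   and `truth`, a data.frame with one row per subject: `id`, `age`, `bmi`,
#'   `ga_recording`, `ga_delivery`, `delivery_mode`, `ttd`, `mean_rr`,
#'   `rmssd_true`, `lf_hf_true`, `quality_ok`. Attribute `"planted"` holds
#'   the achieved sample Spearman of each true parameter against TTD.
#' @export
generate_cohort <- function(spec, synthesize = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  if (diff(spec$ttd_range) == 0 && n > 1 &&
      length(spec$effect_map) && any(spec$effect_map != 0)) {
    warning("degenerate ttd_range: planted correlation undefined against a constant")
  }

  draws <- with_seed(spec$seed, {
    u_ttd <- stats::runif(n)
    z_ttd <- stats::qnorm(u_ttd)
    p_for <- function(metric) {
      rho <- unname(spec$effect_map[metric])
      if (is.null(rho) || is.na(rho) || rho == 0) return(stats::runif(n))
      r_p <- spearman_to_pearson(rho)
      stats::pnorm(r_p * z_ttd + sqrt(1 - r_p^2) * stats::rnorm(n))
    }
    p_rmssd <- p_for("rmssd")
    p_lfhf <- p_for("lf_hf")
    list(
      ttd = spec$ttd_range[1] + u_ttd * diff(spec$ttd_range),
      # truncated-quantile marginals keep values physiological while
      # remaining monotone in the latent percentile
      rmssd = 25 + 13 * stats::qnorm(0.10 + 0.80 * p_rmssd),
      lf_hf = stats::qlnorm(0.02 + 0.96 * p_lfhf,
                            meanlog = log(0.5), sdlog = 0.7),
      mean_rr = pmin(1000, pmax(600, stats::rnorm(n, spec$mean_rr_mean,
                                                  spec$mean_rr_sd))),
      age = round(stats::rnorm(n, 29, 5), 1),
      bmi = round(stats::rnorm(n, 29, 4), 1),
      ga_delivery = pmin(42, pmax(37, stats::rnorm(n, 40, 1.2))),
      mode = sample(names(spec$delivery_mode_probs), n, replace = TRUE,
                    prob = spec$delivery_mode_probs),
      subject_seeds = sample.int(2^31 - 2, n)
    )
  })

  truth <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    age = draws$age,
    bmi = draws$bmi,
    ga_recording = draws$ga_delivery - draws$ttd,
    ga_delivery = draws$ga_delivery,
    delivery_mode = draws$mode,
    ttd = draws$ttd,
    mean_rr = draws$mean_rr,
    rmssd_true = draws$rmssd,
    lf_hf_true = draws$lf_hf,
    quality_ok = TRUE,
    stringsAsFactors = FALSE
  )
  attr(truth, "planted") <- suppressWarnings(c(
    rmssd = stats::cor(draws$rmssd, draws$ttd, method = "spearman"),
    lf_hf = stats::cor(draws$lf_hf, draws$ttd, method = "spearman")
  ))

  recordings <- NULL
  if (synthesize) {
    recordings <- vector("list", n)
    for (i in seq_len(n)) {
      mods <- cohort_modulations(draws$mean_rr[i], draws$rmssd[i],
                                 draws$lf_hf[i])
      sim <- generate_rri_ipfm(tachogram_spec(
        mean_rr = draws$mean_rr[i], modulations = mods,
        duration = spec$duration, seed = draws$subject_seeds[i]
      ))
      recordings[[i]] <- synthesize_ecg(
        sim$beat_times, fs = spec$fs, noise_sd = spec$noise_sd,
        seed = draws$subject_seeds[i],
        subject = list(id = truth$id[i], age = truth$age[i],
                       bmi = truth$bmi[i],
                       ga_recording = truth$ga_recording[i],
                       ga_delivery = truth$ga_delivery[i],
                       delivery_mode = truth$delivery_mode[i],
                       dataset = "synthetic")
      )
    }
  }
  list(recordings = recordings, truth = truth)
}

# Tone amplitudes (relative units) realizing a target RMSSD (ms) and LF/HF
# ratio for an IPFM tachogram with tones at 0.01 (VLF), 0.10 (LF) and
# 0.25 Hz (HF). For tone amplitude A ms at frequency f, successive-difference
# RMS is sqrt(2) * A * |sin(pi f Tbar)| and band power A^2/2, so
# rmssd^2 = 2 A_hf^2 (s_hf^2 + L s_lf^2) with A_lf = sqrt(L) A_hf.
cohort_modulations <- function(mean_rr, rmssd, lf_hf) {
  tbar <- mean_rr / 1000
  s_hf <- abs(sin(pi * 0.25 * tbar))
  s_lf <- abs(sin(pi * 0.10 * tbar))
  a_hf_ms <- rmssd / sqrt(2 * (s_hf^2 + lf_hf * s_lf^2))
  a_lf_ms <- sqrt(lf_hf) * a_hf_ms
  a_vlf_ms <- 12
  list(c(0.01, a_vlf_ms / mean_rr),
       c(0.10, a_lf_ms / mean_rr),
       c(0.25, a_hf_ms / mean_rr))
}
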
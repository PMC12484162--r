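rri_from_ms <- function(x) rri_series(x, c(0, cumsum(x)) / 1000)

test_that("time-domain indices match hand-computed values", {
  td <- time_domain(rri_from_ms(c(600, 600, 600)))
  expect_equal(td$mean_rr, 600)
  expect_equal(td$sdnn, 0)
  expect_equal(td$rmssd, 0)
  expect_equal(time_domain(rri_from_ms(c(600, 610)))$rmssd, 10)
  td3 <- time_domain(rri_from_ms(c(600, 610, 590)))
  expect_equal(td3$rmssd, sqrt((10^2 + 20^2) / 2))  # 15.811
  expect_equal(td3$sdnn, 10)
  expect_error(time_domain(rri_from_ms(700)), "at least 2")
})

test_that("time-domain indices agree with the direct-formula oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    x <- 600 + 120 * runif(sample(10:400, 1))
    td <- time_domain(x)
    orc <- oracle_time_domain(x)
    expect_equal(td$mean_rr, orc$mean_rr, tolerance = 1e-12)
    expect_equal(td$sdnn, orc$sdnn, tolerance = 1e-12)
    expect_equal(td$rmssd, orc$rmssd, tolerance = 1e-12)
  }
})

test_that("SDNN/RMSSD invariances: time reversal and constant offsets", {
  set.seed(33)
  x <- 700 + 80 * rnorm(100)
  td <- time_domain(x)
  td_rev <- time_domain(rev(x))
  expect_equal(td_rev$sdnn, td$sdnn)
  expect_equal(td_rev$rmssd, td$rmssd)
  td_off <- time_domain(x + 55)
  expect_equal(td_off$rmssd, td$rmssd)
  expect_equal(td_off$sdnn, td$sdnn)
})

test_that("tachogram resampling is exact on constants and follows grid arithmetic", {
  rri <- rri_from_ms(rep(800, 50))
  tach <- resample_tachogram(rri)
  expect_equal(tach$values, rep(800, length(tach$values)), tolerance = 1e-9)
  span <- rri$beat_times[51] - rri$beat_times[2]
  expect_length(tach$values, floor(span * 4) + 1)
  expect_error(resample_tachogram(rri_from_ms(c(800, 800))), "at least 4")
})

test_that("resampled tachogram tracks the generating modulation", {
  sim <- generate_rri_ipfm(tachogram_spec(800, list(c(0.1, 0.05)), 300, 19))
  tach <- resample_tachogram(sim$rri)
  tt <- tach$t0 + (seq_along(tach$values) - 1) / tach$fs_interp
  # IPFM with tone a sin(2 pi f t + phi) modulates intervals ~ -a sin(...),
  # lagged by about half a beat; project onto the quadrature pair so the
  # coherence with the generating tone is phase-free
  s <- sin(2 * pi * 0.1 * tt + sim$truth$phases[1])
  q <- cos(2 * pi * 0.1 * tt + sim$truth$phases[1])
  coherence <- sqrt(cor(tach$values, s)^2 + cor(tach$values, q)^2)
  expect_gt(coherence, 0.99)
})

test_that("Welch estimate localizes a pure tone and recovers its power", {
  fs <- 4
  tt <- seq(0, 600, by = 1 / fs)
  A <- 30
  tach <- structure(list(values = A * sin(2 * pi * 0.25 * tt) + 800,
                         fs_interp = fs, t0 = 0), class = "tachogram")
  psd <- estimate_psd(tach)
  peak_f <- psd$freqs[which.max(psd$power_density)]
  expect_lte(abs(peak_f - 0.25), psd$resolution)
  total <- sum(diff(psd$freqs) *
                 (psd$power_density[-length(psd$power_density)] +
                    psd$power_density[-1]) / 2)
  expect_equal(total, A^2 / 2, tolerance = 0.1)
})

test_that("Welch estimate integrates white noise to its variance", {
  set.seed(77)
  x <- rnorm(2400, sd = 25)
  tach <- structure(list(values = x, fs_interp = 4, t0 = 0),
                    class = "tachogram")
  psd <- estimate_psd(tach)
  total <- sum(diff(psd$freqs) *
                 (psd$power_density[-length(psd$power_density)] +
                    psd$power_density[-1]) / 2)
  expect_equal(total, var(x), tolerance = 0.15)
})

test_that("constant tachogram has near-zero power; short tachogram errors", {
  tach <- structure(list(values = rep(800, 1201), fs_interp = 4, t0 = 0),
                    class = "tachogram")
  psd <- estimate_psd(tach)
  expect_lt(max(psd$power_density), 1e-12)
  short <- structure(list(values = rnorm(100), fs_interp = 4, t0 = 0),
                     class = "tachogram")
  expect_error(estimate_psd(short), "shorter than one analysis window")
})

test_that("band powers use the standard band edges and split power correctly", {
  bands <- hrv_bands()
  expect_equal(bands$vlf, c(0.0033, 0.04))
  expect_equal(bands$lf, c(0.04, 0.15))
  expect_equal(bands$hf, c(0.15, 0.4))
  sim <- generate_rri_ipfm(tachogram_spec(800, list(c(0.25, 0.05)), 300, 23))
  psd <- estimate_psd(resample_tachogram(sim$rri))
  bp <- band_powers(psd)
  expect_identical(attr(bp, "bands"), bands)
  raw <- attr(bp, "raw_powers")
  expect_gt(raw[["hf"]], 0.9 * sum(raw))
  expect_lt(bp$lf_hf, 0.1)
})

test_that("matched LF and HF tones give LF/HF near one", {
  # equal planted interval-series band power: the integrate-and-fire
  # sampling attenuates a rate tone at f by sinc(pi f Tbar), so rate
  # amplitudes are pre-compensated to plant equal tachogram power
  tbar <- 0.8
  sinc <- function(f) sin(pi * f * tbar) / (pi * f * tbar)
  a <- 0.04
  sim <- generate_rri_ipfm(tachogram_spec(
    800, list(c(0.1, a / sinc(0.1)), c(0.25, a / sinc(0.25))), 600, 29))
  bp <- band_powers(estimate_psd(resample_tachogram(sim$rri)))
  expect_equal(bp$lf_hf, 1, tolerance = 0.1)
})

test_that("compute_hrv orchestrates all stages consistently", {
  sim <- hf_lf_sim()
  m <- compute_hrv(sim$rri)
  expect_s3_class(m, "hrv_metrics")
  # ratio identity: LF/HF from raw powers equals exp(lf_ln - hf_ln)
  expect_equal(m$lf_hf, exp(m$lf_ln - m$hf_ln), tolerance = 1e-12)
  # unmodulated input: essentially zero variability
  flat <- generate_rri_ipfm(tachogram_spec(800, list(), 310, 1))
  mf <- compute_hrv(flat$rri)
  expect_lt(mf$sdnn, 1)
  expect_lt(mf$rmssd, 1)
})

test_that("HF band power matches the planted tone power", {
  a <- 0.05
  sim <- generate_rri_ipfm(tachogram_spec(800, list(c(0.25, a)), 310, 31))
  m <- compute_hrv(sim$rri)
  planted <- (a * 800)^2 / 2     # tone amplitude a*Tbar ms -> power A^2/2
  expect_lt(abs(m$hf_ln - log(planted)), 0.2)
})

test_that("metrics are invariant to a constant shift of all beat times", {
  sim <- hf_lf_sim()
  shifted <- rri_series(sim$rri$intervals, sim$rri$beat_times + 1234.5,
                        sim$rri$labels)
  m0 <- compute_hrv(sim$rri)
  m1 <- compute_hrv(shifted)
  expect_equal(unclass(m1), unclass(m0), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("full parameter recovery through the noise-free signal chain", {
  sim <- hf_lf_sim()
  rec <- synthesize_ecg(sim$beat_times, fs = 1000, noise_sd = 0)
  peaks <- detect_rpeaks(normalize_amplitude(highpass_filter(rec)))
  rri <- peaks_to_rri(peaks)
  rri <- correct_ectopics(rri, flag_ectopics(rri))
  m <- compute_hrv(rri)
  truth <- sim$truth$true_metrics
  expect_equal(m$sdnn, truth$sdnn, tolerance = 0.05)
  expect_equal(m$rmssd, truth$rmssd, tolerance = 0.05)
})
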
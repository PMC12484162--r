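# Shared fixtures, built in code at test time.

# A modulated 5-min IPFM simulation (HF + LF tones), cached per session.
hf_lf_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_rri_ipfm(tachogram_spec(
        mean_rr = 800,
        modulations = list(c(0.10, 0.03), c(0.25, 0.05)),
        duration = 310, seed = 101
      ))
    }
    cache
  }
})

# Direct-formula time-domain oracle, deliberately written as explicit sums
# (not via sd/diff) so it is an independent route.
oracle_time_domain <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  sq <- 0
  for (i in 2:n) sq <- sq + (x[i] - x[i - 1])^2
  list(mean_rr = m, sdnn = sqrt(ss / (n - 1)), rmssd = sqrt(sq / (n - 1)))
}

# Fraction of total spectral power falling in each analysis band.
band_fractions <- function(rri, window_s = 150) {
  psd <- estimate_psd(resample_tachogram(rri), window_s = window_s)
  f <- psd$freqs
  p <- psd$power_density
  total <- sum(diff(f) * (p[-length(p)] + p[-1]) / 2)
  raw <- attr(band_powers(psd), "raw_powers")
  raw / total
}
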
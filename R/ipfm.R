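#' Generate an RR-interval series by integral pulse frequency modulation
#'
#' The IPFM model fires a beat each time the integral of a modulated
#' instantaneous rate crosses an integer threshold:
#' beats occur at times \eqn{t_k} with
#' \deqn{\int_0^{t_k} \frac{1 + \sum_i a_i \sin(2\pi f_i t + \phi_i)}{\bar T}\,dt = k,}
#' where \eqn{\bar T} is the mean interbeat interval. Sinusoidal rate
#' modulations therefore translate directly into spectral peaks of the
#' RR series at known frequencies, which is what makes the model the
#' reference generator for testing frequency-domain HRV code.
#'
#' The integral is accumulated on a 1 ms grid (trapezoidal rule) and each
#' integer crossing is located by linear interpolation, so crossing times
#' are accurate to well under 1 ms.
#'
#' @param spec A [tachogram_spec()].
#' @return A list with elements:
#'   \describe{
#'     \item{beat_times}{Beat times in seconds.}
#'     \item{rri}{An [rri_series()] of the simulated intervals (ms).}
#'     \item{truth}{Ground truth: `beat_times`, `true_rri` (ms),
#'       `ectopic_flags` (all `FALSE`), `true_metrics` (mean RR, SDNN,
#'       RMSSD of the true series), `modulations`, `phases`.}
#'   }
#' @examples
#' sim <- generate_rri_ipfm(tachogram_spec(800, list(c(0.25, 0.05)), 300, 1))
#' sim$truth$true_metrics
#' @export
generate_rri_ipfm <- function(spec) {
  stopifnot(inherits(spec, "tachogram_spec"))
  tbar <- spec$mean_rr / 1000          # s
  dt <- 1e-3
  tt <- seq(0, spec$duration, by = dt)
  nmod <- length(spec$modulations)
  phases <- with_seed(spec$seed, stats::runif(nmod, 0, 2 * pi))

  rate <- rep.int(1 / tbar, length(tt))
  for (i in seq_len(nmod)) {
    m <- spec$modulations[[i]]
    rate <- rate + (m[2] / tbar) * sin(2 * pi * m[1] * tt + phases[i])
  }

  # cumulative trapezoidal integral of the rate
  m <- c(0, cumsum((rate[-1L] + rate[-length(rate)]) / 2) * dt)
  n_beats <- floor(m[length(m)])
  if (n_beats < 2L) stop2("duration too short: fewer than 2 beats generated")

  ks <- seq_len(n_beats)
  idx <- findInterval(ks, m)                    # m[idx] <= k < m[idx + 1]
  idx[idx >= length(m)] <- length(m) - 1L
  beat_times <- tt[idx] + (ks - m[idx]) / (m[idx + 1L] - m[idx]) * dt

  true_rri <- diff(beat_times) * 1000
  rri <- rri_series(true_rri, beat_times)
  truth <- list(
    beat_times = beat_times,
    true_rri = true_rri,
    ectopic_flags = rep(FALSE, length(true_rri)),
    true_metrics = time_domain(rri),
    modulations = spec$modulations,
    phases = phases
  )
  list(beat_times = beat_times, rri = rri, truth = truth)
}

#' Inject ectopic beats into an RR series
#'
#' Emulates premature (ectopic) beats: at each chosen site \eqn{k} the
#' interval is shortened by the factor `prematurity` and the following
#' interval absorbs the remainder (the compensatory pause), so total series
#' duration is preserved exactly. Both altered intervals are flagged.
#' Sites are sampled without replacement and kept non-adjacent so that
#' flagged runs never merge.
#'
#' @param rri An [rri_series()].
#' @param n_ectopic Number of ectopic sites; must be < `length(rri) / 4`.
#' @param prematurity Shortening factor in (0, 1); e.g. 0.5 halves the
#'   interval at the site.
#' @param seed Integer seed for site selection.
#' @return A list with elements `rri` (modified [rri_series()], altered
#'   intervals labelled `"ectopic"`) and `flags` (logical per-interval).
#' @export
inject_ectopics <- function(rri, n_ectopic, prematurity = 0.5, seed = 1L) {
  stopifnot(inherits(rri, "rri_series"))
  n <- length(rri$intervals)
  if (n_ectopic == 0L) {
    return(list(rri = rri, flags = rep(FALSE, n)))
  }
  if (prematurity <= 0 || prematurity >= 1) {
    stop2("prematurity must be in (0, 1)")
  }
  if (n_ectopic > n / 4) {
    stop2("too many ectopics for series length (need n_ectopic <= n/4)")
  }

  # sites k in 1..(n-1); k and k+1 are altered; enforce gaps >= 2
  sites <- with_seed(seed, {
    chosen <- integer(0)
    avail <- seq_len(n - 1L)
    for (i in seq_len(n_ectopic)) {
      if (!length(avail)) stop2("cannot place non-adjacent ectopic sites")
      k <- if (length(avail) == 1L) avail else sample(avail, 1L)
      chosen <- c(chosen, k)
      avail <- setdiff(avail, (k - 2L):(k + 2L))
    }
    sort(chosen)
  })

  x <- rri$intervals
  flags <- rep(FALSE, n)
  for (k in sites) {
    delta <- (1 - prematurity) * x[k]
    x[k] <- x[k] - delta
    x[k + 1L] <- x[k + 1L] + delta
    flags[c(k, k + 1L)] <- TRUE
  }
  # beat times shift inside each altered pair; endpoints are unchanged
  bt <- rri$beat_times[1L] + c(0, cumsum(x)) / 1000
  labels <- ifelse(flags, "ectopic", rri$labels)
  list(rri = rri_series(x, bt, labels), flags = flags)
}
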
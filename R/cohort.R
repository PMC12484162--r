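#' Apply cohort exclusion filters
#'
#' Removes subjects who delivered for non-physiological reasons (induction,
#' cesarean section) and those whose recordings failed the R-peak quality
#' screen, logging the count removed per reason. The operation is
#' order-independent and idempotent.
#'
#' @param cohort A data.frame with columns `delivery_mode` (one of
#'   `"spontaneous"`, `"induced"`, `"cesarean"`) and `quality_ok` (logical).
#' @return A list: `cohort` (retained rows) and `log`, a named integer
#'   vector with counts `induced`, `cesarean`, `poor_rpeaks`, `retained`.
#' @export
apply_exclusions <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("delivery_mode", "quality_ok") %in% names(cohort)))
  induced <- cohort$delivery_mode == "induced"
  cesarean <- cohort$delivery_mode == "cesarean"
  poor <- !cohort$quality_ok & !induced & !cesarean
  keep <- !(induced | cesarean | poor)
  if (!any(keep)) stop2("no subjects remain after exclusions")
  list(
    cohort = cohort[keep, , drop = FALSE],
    log = c(induced = sum(induced), cesarean = sum(cesarean),
            poor_rpeaks = sum(poor), retained = sum(keep))
  )
}

#' Time to delivery in weeks
#'
#' The study outcome: gestational age at delivery minus gestational age at
#' recording, both in decimal weeks.
#'
#' @param ga_delivery,ga_recording Gestational ages in decimal weeks
#'   (vectorized).
#' @return Time to delivery in weeks; a negative difference is a data-entry
#'   error and raises one.
#' @export
time_to_delivery <- function(ga_delivery, ga_recording) {
  d <- ga_delivery - ga_recording
  if (any(d < 0, na.rm = TRUE)) {
    stop2("ga_delivery earlier than ga_recording: data entry error")
  }
  d
}

#' Convert weeks + days to decimal weeks
#'
#' @param weeks Completed weeks.
#' @param days Additional days (0--6).
#' @return `weeks + days / 7`.
#' @export
ga_weeks <- function(weeks, days = 0) weeks + days / 7

# Lilliefors statistic: KS distance between the sample ECDF and a normal
# CDF with mean/sd estimated from the sample itself.
lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  max(max(seq_len(n) / n - p), max(p - (seq_len(n) - 1) / n))
}

#' Simulate the Lilliefors null distribution
#'
#' Draws `n_mc` Gaussian samples of size `n`, applying the same
#' mean/sd-estimation step as the test itself, and returns the resulting
#' statistics. Reusable across many tests of the same sample size.
#'
#' @param n Sample size.
#' @param n_mc Number of Monte-Carlo replicates (default 10000).
#' @param seed Integer seed.
#' @return Numeric vector of `n_mc` null statistics.
#' @export
lilliefors_null <- function(n, n_mc = 10000L, seed = 1L) {
  with_seed(seed, vapply(seq_len(n_mc), function(i)
    lilliefors_stat(stats::rnorm(n)), numeric(1)))
}

#' Lilliefors normality test with a Monte-Carlo null
#'
#' Kolmogorov--Smirnov test of normality with mean and variance estimated
#' from the sample, which invalidates the standard KS null; the p-value is
#' therefore taken from a seeded Monte-Carlo null distribution built by
#' [lilliefors_null()] (or supplied precomputed). Used as the gate that
#' routes cohort variables to rank-based (Spearman) correlation.
#'
#' @param x Numeric sample, `n >= 5`, non-constant.
#' @param n_mc Monte-Carlo replicates for the null (default 10000).
#' @param seed Integer seed for the null simulation.
#' @param null_stats Optional precomputed null statistics for this sample
#'   size (from [lilliefors_null()]); overrides `n_mc`/`seed`.
#' @return A list: `statistic` (KS distance, in [0, 1]), `p` (Monte-Carlo
#'   p-value), `n`, `n_mc`.
#' @export
lilliefors_test <- function(x, n_mc = 10000L, seed = 1L, null_stats = NULL) {
  x <- x[is.finite(x)]
  if (length(x) < 5L) stop2("need at least 5 observations")
  if (stats::sd(x) == 0) stop2("constant sample: normality test undefined")
  d <- lilliefors_stat(x)
  if (is.null(null_stats)) null_stats <- lilliefors_null(length(x), n_mc, seed)
  list(statistic = d,
       p = (1 + sum(null_stats >= d)) / (length(null_stats) + 1),
       n = length(x), n_mc = length(null_stats))
}

# All permutations of 1..n as an n! x n matrix (n <= 9).
permutations_n <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_n(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * nrow(sub) + 1L):(i * nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Spearman correlation with confidence interval
#'
#' Spearman's rho computed as the product-moment correlation of mid-ranks
#' (average ranks for ties). The p-value is exact for small samples --
#' full enumeration of all `n!` orderings for `n <= 9`, two-sided as the
#' proportion of permutations with `|rho|` at least as large as observed --
#' and a t-approximation (`t = r sqrt((n-2)/(1-r^2))` on `n - 2` df)
#' otherwise. The confidence interval uses the Fisher z transform with the
#' Bonett--Wright standard error `sqrt((1 + rho^2/2)/(n - 3))`.
#'
#' @param x,y Numeric samples of equal length, `n >= 4`, non-constant.
#' @param alpha Two-sided significance level for the CI (default 0.05).
#' @return A list of class `correlation_result`: `r`, `p`, `ci_low`,
#'   `ci_high`, `n`, `method` (`"exact-permutation"` or `"t-approximation"`).
#' @export
spearman_with_ci <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop2("need at least 4 paired observations")
  if (length(y) != n) stop2("x and y must have equal length")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop2("constant sample: Spearman correlation undefined")
  }
  r <- stats::cor(rx, ry)

  if (n <= 9L) {
    perms <- permutations_n(n)
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    # rho for every permutation of y against fixed x, vectorized
    num <- as.vector(matrix(ryc[perms], nrow(perms), n) %*% rxc)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_perm <- num / denom
    p <- mean(abs(rho_perm) >= abs(r) - 1e-12)
    method <- "exact-permutation"
  } else {
    tstat <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }

  rc <- max(-1 + 1e-15, min(1 - 1e-15, r))
  if (n > 3L) {
    se <- sqrt((1 + rc^2 / 2) / (n - 3))
    zq <- stats::qnorm(1 - alpha / 2)
    ci <- tanh(atanh(rc) + c(-1, 1) * zq * se)
  } else {
    ci <- c(-1, 1)
  }
  structure(list(r = r, p = p, ci_low = ci[1], ci_high = ci[2], n = n,
                 method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f [CI: %.3f to %.3f], p = %.4g, n = %d (%s)\n",
              x$r, x$ci_low, x$ci_high, x$p, x$n, x$method))
  invisible(x)
}

hrv_metric_columns <- c(mean_rr = "RR (ms)", sdnn = "SDNN (ms)",
                        rmssd = "RMSSD (ms)", vlf_ln = "VLF (Ln)",
                        lf_ln = "LF (Ln)", hf_ln = "HF (Ln)",
                        lf_hf = "LF/HF")

#' Correlation table of HRV metrics against gestational outcomes
#'
#' For each HRV metric (RR, SDNN, RMSSD, VLF, LF, HF as ln power, LF/HF)
#' and each outcome (GA at recording, GA at delivery, time to delivery),
#' computes a Spearman correlation with CI via [spearman_with_ci()], plus a
#' mean +/- SD summary column. Time to delivery is the primary outcome; the
#' others are reported for completeness.
#'
#' @param cohort A data.frame with metric columns (`mean_rr`, `sdnn`,
#'   `rmssd`, `vlf_ln`, `lf_ln`, `hf_ln`, `lf_hf`) and outcome columns
#'   (`ga_recording`, `ga_delivery`, `ttd`).
#' @param adjust Optional p-value adjustment across the primary-outcome
#'   column: `"none"` (default, matching the exploratory analysis) or
#'   `"BH"` for Benjamini--Hochberg, reported in column `p_ttd_adj`.
#' @param alpha CI level passed to [spearman_with_ci()].
#' @return A data.frame of class `hrv_correlation_table`, one row per
#'   metric: `metric`, `mean`, `sd`, then `r`/`ci_low`/`ci_high`/`p`/`n`
#'   for each outcome suffix (`_ga_rec`, `_ga_del`, `_ttd`). Attribute
#'   `primary_outcome = "ttd"`.
#' @export
correlation_table <- function(cohort, adjust = c("none", "BH"),
                              alpha = 0.05) {
  adjust <- match.arg(adjust)
  metrics <- names(hrv_metric_columns)
  outcomes <- c(ga_rec = "ga_recording", ga_del = "ga_delivery", ttd = "ttd")
  missing_cols <- setdiff(c(metrics, unname(outcomes)), names(cohort))
  if (length(missing_cols)) {
    stop2("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(metric = unname(hrv_metric_columns),
                    mean = vapply(metrics, function(m)
                      mean(cohort[[m]], na.rm = TRUE), numeric(1)),
                    sd = vapply(metrics, function(m)
                      stats::sd(cohort[[m]], na.rm = TRUE), numeric(1)),
                    stringsAsFactors = FALSE)
  for (suf in names(outcomes)) {
    res <- lapply(metrics, function(m)
      spearman_with_ci(cohort[[m]], cohort[[outcomes[[suf]]]], alpha))
    out[[paste0("r_", suf)]] <- vapply(res, `[[`, numeric(1), "r")
    out[[paste0("ci_low_", suf)]] <- vapply(res, `[[`, numeric(1), "ci_low")
    out[[paste0("ci_high_", suf)]] <- vapply(res, `[[`, numeric(1), "ci_high")
    out[[paste0("p_", suf)]] <- vapply(res, `[[`, numeric(1), "p")
    out[[paste0("n_", suf)]] <- vapply(res, `[[`, integer(1), "n")
  }
  if (adjust == "BH") out$p_ttd_adj <- stats::p.adjust(out$p_ttd, "BH")
  structure(out, primary_outcome = "ttd", class = c("hrv_correlation_table",
                                                    "data.frame"))
}

#' @export
print.hrv_correlation_table <- function(x, ...) {
  cat("Correlations of HRV metrics with gestational outcomes",
      "(primary outcome: time to delivery)\n\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-10s %6.2f +- %5.2f   ttd: r = %+.2f [%+.2f, %+.2f] p = %.4g\n",
                x$metric[i], x$mean[i], x$sd[i], x$r_ttd[i],
                x$ci_low_ttd[i], x$ci_high_ttd[i], x$p_ttd[i]))
  }
  invisible(x)
}

#' Demographics summary by group
#'
#' Count plus mean +/- SD of age, BMI, GA at recording and GA at delivery
#' per group (e.g. per source dataset).
#'
#' @param cohort A data.frame with columns `age`, `bmi`, `ga_recording`,
#'   `ga_delivery` and the grouping column.
#' @param group_by Name of the grouping column (default `"dataset"`; if
#'   absent, a single group `"all"` is used).
#' @return A data.frame: one row per (group, feature) with `n`, `mean`,
#'   `sd` (0 with `sd_defined = FALSE` for single-subject groups).
#' @export
demographics_summary <- function(cohort, group_by = "dataset") {
  feats <- c("age", "bmi", "ga_recording", "ga_delivery")
  g <- if (group_by %in% names(cohort)) as.character(cohort[[group_by]])
       else rep("all", nrow(cohort))
  out <- do.call(rbind, lapply(unique(g), function(grp) {
    rows <- cohort[g == grp, , drop = FALSE]
    do.call(rbind, lapply(feats, function(f) {
      v <- rows[[f]]
      v <- v[is.finite(v)]
      data.frame(group = grp, feature = f, n = nrow(rows),
                 n_available = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1L) stats::sd(v) else 0,
                 sd_defined = length(v) > 1L,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
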
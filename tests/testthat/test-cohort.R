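roster <- function(n, n_induced = 0, n_cesarean = 0, n_poor = 0) {
  mode <- rep("spontaneous", n)
  if (n_induced) mode[seq_len(n_induced)] <- "induced"
  if (n_cesarean) mode[n_induced + seq_len(n_cesarean)] <- "cesarean"
  ok <- rep(TRUE, n)
  if (n_poor) ok[n_induced + n_cesarean + seq_len(n_poor)] <- FALSE
  data.frame(id = sprintf("P%02d", seq_len(n)), delivery_mode = mode,
             quality_ok = ok, stringsAsFactors = FALSE)
}

test_that("exclusion filter reproduces the documented cohort arithmetic", {
  # EHG cohort: 45 subjects, 4 induced, 6 cesarean, 10 poor R peaks -> 25
  ex1 <- apply_exclusions(roster(45, 4, 6, 10))
  expect_equal(unname(ex1$log["retained"]), 25)
  expect_equal(unname(ex1$log["induced"]), 4)
  expect_equal(unname(ex1$log["cesarean"]), 6)
  expect_equal(unname(ex1$log["poor_rpeaks"]), 10)
  # ECG cohort: 52 subjects, 40 non-physiological deliveries -> 12
  ex2 <- apply_exclusions(roster(52, 24, 16, 0))
  expect_equal(unname(ex2$log["retained"]), 12)
})

test_that("exclusions are idempotent, order-independent, and identity on clean cohorts", {
  clean <- roster(10)
  expect_identical(apply_exclusions(clean)$cohort, clean)
  r <- roster(30, 3, 4, 5)
  once <- apply_exclusions(r)
  twice <- apply_exclusions(once$cohort)
  expect_identical(twice$cohort, once$cohort)
  expect_equal(sum(twice$log[c("induced", "cesarean", "poor_rpeaks")]), 0)
  shuffled <- r[rev(seq_len(nrow(r))), ]
  expect_setequal(apply_exclusions(shuffled)$cohort$id, once$cohort$id)
  expect_error(apply_exclusions(roster(4, 4, 0, 0)), "no subjects remain")
})

test_that("time to delivery is the GA difference in decimal weeks", {
  expect_equal(time_to_delivery(40, 35), 5)
  expect_equal(time_to_delivery(39, 39), 0)
  # 40 weeks + 2 days vs 38 weeks: 16/7 weeks
  expect_equal(time_to_delivery(ga_weeks(40, 2), 38), 16 / 7)
  expect_equal(time_to_delivery(c(40, 41), c(38, 36)), c(2, 5))
  expect_error(time_to_delivery(38, 40), "data entry")
})

test_that("Lilliefors statistic is a KS distance and matches an independent implementation", {
  skip_if_not_installed("nortest")
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(40 + 10 * seed, mean = 5, sd = 2)
    res <- lilliefors_test(x, n_mc = 50, seed = 1)
    expect_gte(res$statistic, 0)
    expect_lte(res$statistic, 1)
    expect_equal(res$statistic, unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-12)
  }
  expect_error(lilliefors_test(rep(3, 10)), "constant")
  expect_error(lilliefors_test(c(1, 2)), "at least 5")
})

test_that("Lilliefors accepts Gaussian samples and rejects uniform ones", {
  null_big <- lilliefors_null(2000, 200, seed = 3)
  set.seed(41)
  p_norm <- replicate(20, lilliefors_test(rnorm(2000),
                                          null_stats = null_big)$p)
  expect_gte(mean(p_norm > 0.05), 0.9)
  # Monte-Carlo power against uniform(0,1) at n = 200 is ~0.95; assert the
  # observed rejection rate is consistent with that at this replicate count
  null_200 <- lilliefors_null(200, 2000, seed = 4)
  set.seed(42)
  p_unif <- replicate(200, lilliefors_test(runif(200),
                                           null_stats = null_200)$p)
  expect_gte(mean(p_unif < 0.05), 0.90)
})

test_that("Spearman handles perfectly monotone data", {
  x <- 1:4
  expect_equal(spearman_with_ci(x, c(10, 20, 30, 40))$r, 1)
  expect_equal(spearman_with_ci(x, c(40, 30, 20, 10))$r, -1)
})

test_that("Spearman rho and exact p match brute-force enumeration (with ties)", {
  cases <- list(
    list(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5)),
    list(x = c(1, 1, 2, 3, 4), y = c(5, 3, 3, 2, 1)),   # ties in both
    list(x = c(2, 7, 1, 8, 2, 8), y = c(3, 1, 4, 1, 5, 9)),
    list(x = c(1, 2, 3, 4, 5, 6, 7), y = c(2, 4, 1, 7, 5, 3, 6))
  )
  for (cs in cases) {
    res <- spearman_with_ci(cs$x, cs$y)
    rx <- rank(cs$x); ry <- rank(cs$y)
    r0 <- cor(rx, ry)
    perms <- laborHRV:::permutations_n(length(cs$x))
    rho <- apply(perms, 1, function(p) cor(rx, ry[p]))
    expect_equal(res$r, r0, tolerance = 1e-12)
    expect_equal(res$p, mean(abs(rho) >= abs(r0) - 1e-12), tolerance = 1e-12)
    expect_identical(res$method, "exact-permutation")
  }
  # n=5, y = 2,1,4,3,5: sum(d^2) = 4 so rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman_with_ci(1:5, c(2, 1, 4, 3, 5))$r, 0.8)
})

test_that("exact permutation p agrees with the classical exact distribution", {
  # cor.test's exact Spearman p (AS 89 full distribution) as oracle, no ties
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(8:9, 1)
    x <- sample(n); y <- sample(n)
    res <- spearman_with_ci(x, y)
    ct <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-9)
  }
})

test_that("large-sample Spearman p tracks the t approximation in cor.test", {
  set.seed(19)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  res <- spearman_with_ci(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_identical(res$method, "t-approximation")
  expect_lt(abs(res$p - ct$p.value), 0.02)
})

test_that("confidence interval brackets rho and degenerate input errors", {
  set.seed(23)
  x <- rnorm(30); y <- x + rnorm(30)
  res <- spearman_with_ci(x, y)
  expect_lte(res$ci_low, res$r)
  expect_gte(res$ci_high, res$r)
  expect_lte(abs(res$r), 1)
  # Bonett-Wright width: wider alpha -> narrower interval
  res90 <- spearman_with_ci(x, y, alpha = 0.10)
  expect_lt(res90$ci_high - res90$ci_low, res$ci_high - res$ci_low)
  expect_error(spearman_with_ci(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_with_ci(1:3, 1:3), "at least 4")
})

synthetic_cohort_df <- function(n, seed, effect = c(lf_hf = 0.55,
                                                    rmssd = -0.50)) {
  co <- generate_cohort(cohort_spec(n, effect_map = effect, seed = seed),
                        synthesize = FALSE)
  tr <- co$truth
  set.seed(seed + 1000)
  data.frame(
    mean_rr = tr$mean_rr, sdnn = 44 + rnorm(n, 0, 14),
    rmssd = tr$rmssd_true, vlf_ln = 6.6 + rnorm(n, 0, 0.6),
    lf_ln = 5.9 + rnorm(n, 0, 0.6), hf_ln = 5.2 + rnorm(n, 0, 1),
    lf_hf = tr$lf_hf_true, ga_recording = tr$ga_recording,
    ga_delivery = tr$ga_delivery, ttd = tr$ttd
  )
}

test_that("correlation table has the full metric-by-outcome structure", {
  df <- synthetic_cohort_df(40, seed = 2)
  tab <- correlation_table(df)
  expect_equal(nrow(tab), 7)
  expect_setequal(tab$metric, c("RR (ms)", "SDNN (ms)", "RMSSD (ms)",
                                "VLF (Ln)", "LF (Ln)", "HF (Ln)", "LF/HF"))
  for (suf in c("ga_rec", "ga_del", "ttd")) {
    expect_true(all(c(paste0("r_", suf), paste0("p_", suf),
                      paste0("ci_low_", suf), paste0("ci_high_", suf),
                      paste0("n_", suf)) %in% names(tab)))
  }
  expect_identical(attr(tab, "primary_outcome"), "ttd")
  expect_true(all(tab$ci_low_ttd <= tab$r_ttd & tab$r_ttd <= tab$ci_high_ttd))
  expect_error(correlation_table(df[, -1]), "missing columns")
  tab_bh <- correlation_table(df, adjust = "BH")
  expect_true(all(tab_bh$p_ttd_adj >= tab_bh$p_ttd - 1e-12))
})

test_that("planted correlations are recovered and null cohorts stay quiet", {
  df <- synthetic_cohort_df(200, seed = 5)
  tab <- correlation_table(df)
  expect_lt(abs(tab$r_ttd[tab$metric == "LF/HF"] - 0.55), 0.15)
  expect_lt(abs(tab$r_ttd[tab$metric == "RMSSD (ms)"] - (-0.50)), 0.15)
  # null cohort: no metric strongly correlated
  df0 <- synthetic_cohort_df(37, seed = 6, effect = numeric(0))
  tab0 <- correlation_table(df0)
  expect_lt(max(abs(tab0$r_ttd)), 0.5)
})

test_that("demographics summary reports mean +/- SD per group", {
  df <- data.frame(age = c(27, 29, 32), bmi = c(29, 28, 31),
                   ga_recording = c(35, 36, 38), ga_delivery = c(40, 39, 39),
                   dataset = c("A", "A", "B"))
  s <- demographics_summary(df)
  expect_equal(sort(unique(s$group)), c("A", "B"))
  a_age <- s[s$group == "A" & s$feature == "age", ]
  expect_equal(a_age$n, 2)
  expect_equal(a_age$mean, 28)
  expect_equal(a_age$sd, sd(c(27, 29)))
  b_age <- s[s$group == "B" & s$feature == "age", ]
  expect_equal(b_age$mean, 32)
  expect_equal(b_age$sd, 0)
  expect_false(b_age$sd_defined)
  # missing grouping column: single pooled group
  expect_equal(unique(demographics_summary(df[, -5])$group), "all")
})
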
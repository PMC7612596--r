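test_that("log differences behave as an antisymmetric paired transform", {
  s <- paired_sample(c(2, 2.2, 1.9, 2.4), c(2, 2.2, 1.9, 2.4),
                     "MBP", "suv_mean")
  d <- log_differences(s)
  expect_equal(d$d_ln, rep(0, 4))
  expect_equal(d$sd_d_ln, 0)

  s2 <- paired_sample(c(1, 1), exp(1) * c(1, 1), "MBP", "suv_mean")
  d2 <- log_differences(s2)
  expect_equal(d2$d_ln, c(1, 1))
  expect_equal(d2$mean_d_ln, 1)
  expect_equal(d2$sd_d_ln, 0)

  set.seed(21)
  a <- rlnorm(10); b <- rlnorm(10)
  fwd <- log_differences(paired_sample(a, b))
  rev <- log_differences(paired_sample(b, a))
  expect_equal(fwd$d_ln, -rev$d_ln)

  expect_error(paired_sample(c(1, -2), c(1, 1), "BM", "suv_mean"),
               class = "suvrepeat_log_domain")
  expect_error(paired_sample(c(1, 2), 1),
               class = "suvrepeat_invalid_sample")
  expect_error(paired_sample(c(1), c(1)),
               class = "suvrepeat_insufficient_data")
})

test_that("within-subject SD and wCV follow the log-scale formulas", {
  z <- log_differences(paired_sample(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(within_subject_sd(z), 0)

  # sd(d_ln) = sqrt(2) divides to exactly 1
  d <- structure(list(d_ln = c(0, 2), mean_d_ln = 1, sd_d_ln = sqrt(2),
                      n = 2L), class = "log_diffs")
  expect_equal(within_subject_sd(d), 1)

  expect_equal(wcv_percent(0), 0)
  expect_equal(wcv_percent(log(2)), 100)
  # round-trips the printed two-decimal wCV of a low-variability tissue
  expect_equal(round(wcv_percent(0.0983), 2), 10.33)
  expect_error(wcv_percent(-0.1), class = "suvrepeat_domain")

  # Monte-Carlo: with per-measurement log-noise sigma, the difference of
  # two measurements has SD sigma*sqrt(2), so wSD estimates sigma
  set.seed(31)
  sigma <- 0.12
  truth <- rnorm(4000, log(2), 0.3)
  s1 <- exp(truth + rnorm(4000, 0, sigma))
  s2 <- exp(truth + rnorm(4000, 0, sigma))
  wsd <- within_subject_sd(log_differences(paired_sample(s1, s2)))
  expect_equal(wsd, sigma, tolerance = 0.05)
})

test_that("repeatability coefficients reproduce printed reference values", {
  # wCV = 0 collapses both limits
  expect_equal(repeatability_coefficients(0), c(upper = 0, lower = 0))

  # mediastinal blood pool SUVmean, interobserver arm: wCV 6.10%
  rc <- repeatability_coefficients(sqrt(2) * log(1 + 6.10 / 100))
  expect_equal(rc[["upper"]], 17.84, tolerance = 0.05 / 17.84)
  expect_equal(rc[["lower"]], -15.14, tolerance = 0.05 / 15.14)

  # mediastinal blood pool SUVpeak, test-retest arm: wCV 9.56%
  rc2 <- repeatability_coefficients(sqrt(2) * log(1 + 9.56 / 100))
  expect_equal(rc2[["lower"]], -22.36, tolerance = 0.05 / 22.36)
  expect_equal(rc2[["upper"]], 28.81, tolerance = 0.05 / 28.81)

  # reciprocal symmetry holds to machine precision for any sd
  for (sd in c(0.01, 0.1, 0.5, 1.2)) {
    r <- repeatability_coefficients(sd)
    expect_equal((1 + r[["upper"]] / 100) * (1 + r[["lower"]] / 100), 1,
                 tolerance = 1e-12)
  }
})

test_that("wCV and RC are linked by the exact round-trip identity", {
  set.seed(41)
  for (i in 1:20) {
    s1 <- rlnorm(10); s2 <- s1 * exp(rnorm(10, 0, 0.2))
    d <- log_differences(paired_sample(s1, s2))
    wcv <- wcv_percent(within_subject_sd(d))
    rc <- repeatability_coefficients(d)
    expect_equal(rc[["upper"]],
                 ((1 + wcv / 100)^(1.96 * sqrt(2)) - 1) * 100,
                 tolerance = 1e-12)
  }
})

test_that("chi-square CI for the RC matches published quantiles and brackets the point estimate", {
  # independent recomputation from chi-square quantiles at 21 df
  d <- structure(list(d_ln = numeric(22), mean_d_ln = 0, sd_d_ln = 0.1,
                      n = 22L), class = "log_diffs")
  ci <- rc_confidence_intervals(d)
  sd_lo <- 0.1 * sqrt(21 / qchisq(0.975, 21))
  sd_hi <- 0.1 * sqrt(21 / qchisq(0.025, 21))
  expect_equal(ci$sd_ci, c(sd_lo, sd_hi), tolerance = 1e-12)
  expect_equal(ci$upper, (exp(1.96 * c(sd_lo, sd_hi)) - 1) * 100,
               tolerance = 1e-12)
  expect_equal(ci$lower, (exp(-1.96 * c(sd_hi, sd_lo)) - 1) * 100,
               tolerance = 1e-12)

  # the interval brackets the point RC and narrows with n
  rc <- repeatability_coefficients(d)
  expect_lt(ci$upper[1], rc[["upper"]]); expect_gt(ci$upper[2], rc[["upper"]])
  expect_lt(ci$lower[1], rc[["lower"]]); expect_gt(ci$lower[2], rc[["lower"]])
  d2 <- d; d2$n <- 200L
  ci2 <- rc_confidence_intervals(d2)
  expect_lt(diff(ci2$upper), diff(ci$upper))
})

test_that("chi-square CI achieves near-nominal coverage for the true RC", {
  set.seed(51)
  sigma_d <- 0.2
  true_rc <- (exp(1.96 * sigma_d) - 1) * 100
  hits <- 0L
  reps <- 1000L
  for (i in seq_len(reps)) {
    dl <- rnorm(22, 0, sigma_d)
    d <- structure(list(d_ln = dl, mean_d_ln = mean(dl), sd_d_ln = sd(dl),
                        n = 22L), class = "log_diffs")
    ci <- rc_confidence_intervals(d)
    if (ci$upper[1] <= true_rc && true_rc <= ci$upper[2]) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.925)
  expect_lt(hits / reps, 0.975)
})

test_that("paired tests handle symmetry, degeneracy and small-sample exactness", {
  # perfectly antisymmetric log differences: t statistic 0, p = 1
  x <- c(1, 2, 3, 4)
  s <- paired_sample(exp(x), exp(c(x[1] + 0.3, x[2] - 0.3,
                                   x[3] + 0.6, x[4] - 0.6)))
  pt_res <- paired_tests(s)
  expect_equal(pt_res$t_log, 0, tolerance = 1e-12)
  expect_equal(pt_res$p_t_log, 1, tolerance = 1e-12)

  # identical pairs: all-zero differences make Wilcoxon not applicable
  s0 <- paired_sample(c(2, 3, 4), c(2, 3, 4))
  r0 <- paired_tests(s0)
  expect_true(is.na(r0$p_wilcoxon))
  expect_equal(r0$p_t_log, 1)

  # a fixed 6-pair vector matches the exact sign-flip enumeration
  s1 <- c(2.1, 1.8, 3.0, 2.6, 1.2, 2.9)
  s2 <- c(2.45, 1.71, 3.28, 2.91, 1.13, 3.34)
  r <- paired_tests(paired_sample(s1, s2))
  expect_equal(r$p_wilcoxon, bf_signrank_p(s2 - s1), tolerance = 1e-12)
})

test_that("paired t-test holds its nominal type-I error under the null", {
  set.seed(61)
  reps <- 2000L
  rej <- 0L
  for (i in seq_len(reps)) {
    s1 <- exp(rnorm(22, 0.5, 0.3))
    s2 <- s1 * exp(rnorm(22, 0, 0.15))
    if (paired_tests(paired_sample(s1, s2))$p_t_log < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / reps, 0.035)
  expect_lt(rej / reps, 0.065)
})

test_that("trend tests detect proportional bias and respect tie saturation", {
  # difference exactly proportional to the mean: Pearson r = 1
  m <- c(1, 2, 3, 4, 5)
  d <- 0.1 * m
  s1 <- m - d / 2; s2 <- m + d / 2
  tr <- trend_tests(paired_sample(s1, s2))
  expect_equal(tr$pearson_r_orig, 1, tolerance = 1e-9)

  # constant absolute difference saturates the ties: no orderable trend
  # remains, so the tie-corrected tau is reported as not applicable
  s1c <- c(1, 2, 3, 4, 5); s2c <- s1c + 0.5
  trc <- trend_tests(paired_sample(s1c, s2c))
  expect_true(is.na(trc$kendall_tau_orig))

  # tau equals the exhaustive concordant/discordant pair count
  set.seed(71)
  for (i in 1:5) {
    a <- rlnorm(10); b <- a * exp(rnorm(10, 0, 0.3))
    tr2 <- trend_tests(paired_sample(a, b))
    expect_equal(tr2$kendall_tau_orig,
                 bf_tau_b((a + b) / 2, abs(b - a)), tolerance = 1e-12)
    expect_equal(tr2$kendall_tau_log,
                 bf_tau_b((log(a) + log(b)) / 2, abs(log(b) - log(a))),
                 tolerance = 1e-12)
  }

  # zero-variance axis: correlations reported as not applicable
  sz <- paired_sample(c(2, 2, 2), c(2, 2, 2))
  trz <- trend_tests(sz)
  expect_true(is.na(trz$pearson_r_orig))
})

test_that("Bonferroni correction reproduces the 33-parameter threshold", {
  fc <- bonferroni(0.05, 33)
  expect_equal(fc$threshold, 0.05 / 33)
  expect_equal(fc$threshold_printed, 0.0015)
  expect_equal(bonferroni(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni(0.05, 50)$threshold, 0.001)
  expect_error(bonferroni(0.05, 0), class = "suvrepeat_domain")
})

test_that("Bland-Altman data are internally consistent and antisymmetric", {
  set.seed(81)
  a <- rlnorm(15, 0.7, 0.2); b <- a * exp(rnorm(15, 0.02, 0.15))
  s <- paired_sample(a, b)
  ba <- bland_altman_data(s)
  d <- log_differences(s)

  # identical pairs sit on the zero line
  ba0 <- bland_altman_data(paired_sample(a, a))
  expect_equal(ba0$points$d_ln, rep(0, 15))
  expect_equal(ba0$bias, 0)

  # the plot limits agree with the percent-scale repeatability bounds
  rc <- repeatability_coefficients(d)
  expect_equal((exp(ba$rc_ln[["upper"]] - ba$bias) - 1) * 100,
               rc[["upper"]], tolerance = 1e-12)
  expect_equal((exp(ba$rc_ln[["lower"]] - ba$bias) - 1) * 100,
               rc[["lower"]], tolerance = 1e-12)

  # swapping the scans mirrors the plot about zero
  ba_rev <- bland_altman_data(paired_sample(b, a))
  expect_equal(ba_rev$points$d_ln, -ba$points$d_ln)
  expect_equal(ba_rev$bias, -ba$bias)
  expect_equal(ba_rev$points$mean_ln, ba$points$mean_ln)
})

test_that("cohort analysis is order-invariant and degrades gracefully", {
  meas <- tiny_cohort(seed = 91)
  res <- analyze_cohort(meas, "test_retest")

  # permuting measurement rows leaves every summary unchanged
  set.seed(92)
  shuffled <- meas[sample(nrow(meas)), ]
  res2 <- analyze_cohort(shuffled, "test_retest")
  expect_equal(as.data.frame(res2), as.data.frame(res))

  # duplicating scan 1 as scan 2 gives exactly zero variability
  dup <- meas
  v <- dup$scan_index == 2
  key <- paste(dup$subject_id, dup$observer_id, dup$tissue)
  src <- match(key[v], key[dup$scan_index == 1])
  one <- dup[dup$scan_index == 1, ]
  dup[v, c("suv_max", "suv_mean", "suv_peak")] <-
    one[src, c("suv_max", "suv_mean", "suv_peak")]
  resd <- analyze_cohort(dup, "test_retest")
  expect_true(all(resd$wcv_pct == 0))
  expect_true(all(resd$rc_upper_pct == 0))

  # a tissue left with < 2 pairs yields an NA row plus a warning
  crippled <- meas[!(meas$tissue == "BM" & meas$subject_id != "S01"), ]
  w <- capture_warnings(resc <- analyze_cohort(crippled, "test_retest"))
  expect_true(any(grepl("BM", w)))
  bm <- resc[resc$tissue == "BM", ]
  expect_true(all(is.na(bm$wcv_pct)))
  expect_equal(nrow(resc), nrow(res))
})
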
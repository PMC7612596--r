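#' Aligned per-subject SUV pairs for one tissue and metric
#'
#' The unit of analysis for both the test-retest arm (scan 1 vs scan 2,
#' same observer) and the interobserver arm (observer 1 vs observer 2,
#' same scan). All values must be strictly positive because the
#' repeatability framework works on natural-log differences.
#'
#' @param suv_1,suv_2 Numeric vectors of paired SUV values, aligned by
#'   subject, length >= 2 after exclusions.
#' @param tissue,metric,pairing Labels carried through to reports.
#' @param subject_ids Optional subject identifiers (defaults to 1..n).
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(suv_1, suv_2, tissue = NA_character_,
                          metric = NA_character_,
                          pairing = c("test_retest", "interobserver"),
                          subject_ids = NULL) {
  pairing <- match.arg(pairing)
  if (length(suv_1) != length(suv_2)) {
    stop_suv("invalid_sample", "suv_1 and suv_2 must be the same length")
  }
  n <- length(suv_1)
  if (n < 2L) {
    stop_suv("insufficient_data", sprintf(
      "need at least 2 complete pairs (%s, %s): got %d",
      tissue, metric, n))
  }
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(n))
  bad <- which(!is.finite(suv_1) | !is.finite(suv_2) |
                 suv_1 <= 0 | suv_2 <= 0)
  if (length(bad)) {
    stop_suv("log_domain", sprintf(
      "nonpositive or missing SUV for subject(s) %s (tissue %s, metric %s); log transform requires positive values",
      paste(subject_ids[bad], collapse = ", "), tissue, metric))
  }
  structure(list(suv_1 = as.numeric(suv_1), suv_2 = as.numeric(suv_2),
                 subject_ids = as.character(subject_ids), tissue = tissue,
                 metric = metric, pairing = pairing, n = n),
            class = "paired_sample")
}

as_paired_sample <- function(x, ...) {
  if (inherits(x, "paired_sample")) x else paired_sample(x, ...)
}

#' Per-subject log differences
#'
#' The repeatability analysis runs on `d_ln = ln(SUV_2) - ln(SUV_1)`,
#' motivated by the approximately log-normal distribution of SUV
#' measurements. The summary SD uses the sample (n - 1) denominator.
#'
#' @param sample A [paired_sample()].
#' @return An object of class `log_diffs`: `d_ln`, `mean_d_ln`, `sd_d_ln`,
#'   `n`, plus the sample's labels.
#' @export
#' @examples
#' s <- paired_sample(c(2, 2.2, 1.9), c(2.1, 2.0, 2.2), "MBP", "suv_mean")
#' log_differences(s)$sd_d_ln
log_differences <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  d <- log(sample$suv_2) - log(sample$suv_1)
  structure(list(d_ln = d, mean_d_ln = mean(d), sd_d_ln = stats::sd(d),
                 n = sample$n, tissue = sample$tissue,
                 metric = sample$metric, subject_ids = sample$subject_ids),
            class = "log_diffs")
}

#' Within-subject SD on the log scale
#'
#' A test-retest difference is the difference of two independent
#' measurement errors, so its SD overstates the single-measurement SD by
#' sqrt(2): `wSD_ln = SD(d_ln) / sqrt(2)`.
#'
#' @param diffs A [log_differences()] result.
#' @return The within-subject log-scale SD (scalar).
#' @export
within_subject_sd <- function(diffs) {
  stopifnot(inherits(diffs, "log_diffs"))
  if (diffs$n < 2L) {
    stop_suv("insufficient_data", "within-subject SD needs n >= 2 pairs")
  }
  diffs$sd_d_ln / sqrt(2)
}

#' Within-subject coefficient of variation (percent)
#'
#' Back-transforms the log-scale within-subject SD to a relative scale:
#' `wCV% = (exp(wSD_ln) - 1) * 100`.
#'
#' @param wsd_ln Nonnegative within-subject log-scale SD.
#' @return wCV as a percentage.
#' @export
#' @examples
#' wcv_percent(log(2))  # 100%
wcv_percent <- function(wsd_ln) {
  if (!is.numeric(wsd_ln) || any(!is.finite(wsd_ln)) || any(wsd_ln < 0)) {
    stop_suv("domain", "wsd_ln must be finite and nonnegative")
  }
  (exp(wsd_ln) - 1) * 100
}

rc_from_sd <- function(sd_d_ln, z = 1.96) {
  c(upper = (exp(z * sd_d_ln) - 1) * 100,
    lower = (exp(-z * sd_d_ln) - 1) * 100)
}

#' 95% repeatability coefficients on the percent scale
#'
#' The symmetric log-scale limits `RC_ln = +/- 1.96 * SD(d_ln)` become
#' asymmetric after back-transformation:
#' `RC = (exp(+/- RC_ln) - 1) * 100`. The bounds satisfy the exact
#' reciprocal relation `(1 + upper/100) * (1 + lower/100) = 1`; 95% of
#' repeat measurements are expected to fall between `lower` and `upper`
#' percent of the first measurement.
#'
#' @param diffs A [log_differences()] result, or a bare nonnegative
#'   `SD(d_ln)` scalar.
#' @return Named vector `c(upper =, lower =)` in percent.
#' @export
#' @examples
#' repeatability_coefficients(sqrt(2) * log(1.0610))  # wCV 6.10%
repeatability_coefficients <- function(diffs) {
  sd_d <- if (inherits(diffs, "log_diffs")) {
    if (diffs$n < 2L) stop_suv("insufficient_data", "need n >= 2 pairs")
    diffs$sd_d_ln
  } else {
    if (!is.numeric(diffs) || length(diffs) != 1L || !is.finite(diffs) ||
        diffs < 0) {
      stop_suv("domain", "sd_d_ln must be a nonnegative scalar")
    }
    diffs
  }
  rc_from_sd(sd_d)
}

#' Chi-square confidence intervals for the repeatability coefficients
#'
#' A two-sided CI for the log-difference SD follows from the chi-square
#' sampling distribution of the sample variance:
#' `[sd * sqrt((n-1)/qchisq(1 - a/2, n-1)), sd * sqrt((n-1)/qchisq(a/2, n-1))]`.
#' Because the map from `SD(d_ln)` to each RC bound is monotone, the CI
#' propagates exactly through the exponential back-transformation.
#'
#' @param diffs A [log_differences()] result.
#' @param level Confidence level, default 0.95.
#' @return List with elements `sd_ci` (log scale), `upper` and `lower`
#'   (each a `c(lo, hi)` interval on the percent scale for the
#'   corresponding RC bound).
#' @export
rc_confidence_intervals <- function(diffs, level = 0.95) {
  stopifnot(inherits(diffs, "log_diffs"))
  n <- diffs$n
  if (n < 2L) stop_suv("insufficient_data", "chi-square CI needs n >= 2")
  a <- 1 - level
  df <- n - 1
  sd_lo <- diffs$sd_d_ln * sqrt(df / stats::qchisq(1 - a / 2, df))
  sd_hi <- diffs$sd_d_ln * sqrt(df / stats::qchisq(a / 2, df))
  up <- c(rc_from_sd(sd_lo)[["upper"]], rc_from_sd(sd_hi)[["upper"]])
  lo <- c(rc_from_sd(sd_hi)[["lower"]], rc_from_sd(sd_lo)[["lower"]])
  list(sd_ci = c(sd_lo, sd_hi), upper = up, lower = lo, level = level)
}

#' Bias and normality tests for a paired sample
#'
#' Shapiro-Wilk normality is assessed on the log differences (the scale of
#' the repeatability model). The paired t-test for bias is run on the log
#' differences, with the original-scale t reported as a secondary result;
#' the Wilcoxon signed-rank test runs on the original-scale differences
#' (exact null for n < 25, zero differences dropped, ties mid-ranked with
#' a continuity-corrected normal approximation).
#'
#' @param sample A [paired_sample()].
#' @return List with `p_shapiro`, `p_t_log`, `p_t_orig`, `p_wilcoxon`,
#'   `t_log`, `t_orig`, and `n`. Degenerate cases (constant differences,
#'   all-zero differences) yield `NA` rather than an error.
#' @export
paired_tests <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  d_ln <- log(sample$suv_2) - log(sample$suv_1)
  d_or <- sample$suv_2 - sample$suv_1
  n <- sample$n

  p_shapiro <- if (n >= 3 && stats::sd(d_ln) > 0) {
    stats::shapiro.test(d_ln)$p.value
  } else {
    NA_real_
  }

  tt <- function(d) {
    if (stats::sd(d) == 0) {
      # zero spread: no evidence of bias if all-zero, degenerate otherwise
      return(list(stat = NA_real_, p = if (all(d == 0)) 1 else NA_real_))
    }
    r <- stats::t.test(d)
    list(stat = unname(r$statistic), p = r$p.value)
  }
  t_log <- tt(d_ln)
  t_or <- tt(d_or)

  p_wil <- if (all(d_or == 0)) {
    NA_real_  # signed-rank undefined with no nonzero differences
  } else {
    suppressWarnings(
      stats::wilcox.test(d_or, exact = n < 25, correct = TRUE)$p.value)
  }

  list(p_shapiro = p_shapiro, p_t_log = t_log$p, p_t_orig = t_or$p,
       p_wilcoxon = p_wil, t_log = t_log$stat, t_orig = t_or$stat, n = n)
}

safe_cor <- function(x, y, method) {
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(est = NA_real_, p = NA_real_))
  }
  r <- suppressWarnings(stats::cor.test(x, y, method = method))
  c(est = unname(r$estimate), p = r$p.value)
}

#' Trend of differences (and their spread) against the mean
#'
#' Proportional bias is assessed as the Pearson correlation of the
#' per-subject difference against the per-subject mean, on the original
#' and the log scale (equivalent to testing the regression slope of
#' difference on mean). Heteroscedasticity is assessed as the Kendall
#' tau-b correlation of the *absolute* difference against the mean, again
#' on both scales. All p values are two-sided.
#'
#' @param sample A [paired_sample()].
#' @return Object of class `trend_summary`: `pearson_r_orig`,
#'   `p_pearson_orig`, `pearson_r_log`, `p_pearson_log`,
#'   `kendall_tau_orig`, `p_kendall_orig`, `kendall_tau_log`,
#'   `p_kendall_log`. Zero-variance axes give `NA`.
#' @export
trend_tests <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  if (sample$n < 3L) {
    stop_suv("insufficient_data", "trend tests need n >= 3 pairs")
  }
  d_or <- sample$suv_2 - sample$suv_1
  m_or <- (sample$suv_1 + sample$suv_2) / 2
  d_ln <- log(sample$suv_2) - log(sample$suv_1)
  m_ln <- (log(sample$suv_1) + log(sample$suv_2)) / 2

  po <- safe_cor(m_or, d_or, "pearson")
  pl <- safe_cor(m_ln, d_ln, "pearson")
  ko <- safe_cor(m_or, abs(d_or), "kendall")
  kl <- safe_cor(m_ln, abs(d_ln), "kendall")
  structure(list(
    pearson_r_orig = po[["est"]], p_pearson_orig = po[["p"]],
    pearson_r_log = pl[["est"]], p_pearson_log = pl[["p"]],
    kendall_tau_orig = ko[["est"]], p_kendall_orig = ko[["p"]],
    kendall_tau_log = kl[["est"]], p_kendall_log = kl[["p"]],
    n = sample$n), class = "trend_summary")
}

#' Bonferroni family-wise correction
#'
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_tests Number of tests in the family; for the standard healthy
#'   tissue panel this is 11 tissues x 3 SUV metrics = 33, giving a
#'   per-test threshold printing as 0.0015.
#' @return Object of class `family_correction` with `alpha`, `n_tests`,
#'   `threshold` (exact) and `threshold_printed` (2 significant figures).
#' @export
#' @examples
#' bonferroni(0.05, 33)$threshold_printed
bonferroni <- function(alpha = 0.05, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop_suv("domain", "alpha must be in (0, 1]")
  }
  if (!is.numeric(n_tests) || n_tests < 1 || n_tests != round(n_tests)) {
    stop_suv("domain", "n_tests must be a positive integer")
  }
  thr <- alpha / n_tests
  structure(list(alpha = alpha, n_tests = as.integer(n_tests),
                 threshold = thr, threshold_printed = signif(thr, 2)),
            class = "family_correction")
}

#' Bland-Altman data on the log scale
#'
#' Emits plot-ready per-subject points (mean of the two log-SUVs against
#' the log difference), the bias line with its t-based confidence
#' interval, and the upper/lower repeatability limits
#' `mean(d_ln) +/- 1.96 * SD(d_ln)` with chi-square confidence intervals
#' on the +/-1.96*SD half-width.
#'
#' @param sample A [paired_sample()].
#' @param level Confidence level for the interval annotations.
#' @return List of class `bland_altman`: `points` (data.frame with
#'   `subject_id`, `mean_ln`, `d_ln`), `bias`, `bias_ci`, `rc_ln`
#'   (named upper/lower limits about the bias), `rc_ln_ci_upper`,
#'   `rc_ln_ci_lower`, and `n`.
#' @export
bland_altman_data <- function(sample, level = 0.95) {
  stopifnot(inherits(sample, "paired_sample"))
  d <- log_differences(sample)
  m_ln <- (log(sample$suv_1) + log(sample$suv_2)) / 2
  n <- d$n
  se <- d$sd_d_ln / sqrt(n)
  tcrit <- stats::qt(1 - (1 - level) / 2, n - 1)
  ci <- rc_confidence_intervals(d, level)
  half <- 1.96 * d$sd_d_ln
  out <- list(
    points = data.frame(subject_id = sample$subject_ids, mean_ln = m_ln,
                        d_ln = d$d_ln, stringsAsFactors = FALSE),
    bias = d$mean_d_ln,
    bias_ci = c(d$mean_d_ln - tcrit * se, d$mean_d_ln + tcrit * se),
    rc_ln = c(upper = d$mean_d_ln + half, lower = d$mean_d_ln - half),
    rc_ln_ci_upper = d$mean_d_ln + 1.96 * ci$sd_ci,
    rc_ln_ci_lower = d$mean_d_ln - rev(1.96 * ci$sd_ci),
    n = n)
  class(out) <- "bland_altman"
  out
}
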
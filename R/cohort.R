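MEASUREMENT_COLUMNS <- c("subject_id", "scan_index", "observer_id",
                         "tissue", "suv_max", "suv_mean", "suv_peak",
                         "excluded", "exclusion_reason")

check_measurements <- function(measurements) {
  missing <- setdiff(MEASUREMENT_COLUMNS, names(measurements))
  if (length(missing)) {
    stop_suv("invalid_measurements", sprintf(
      "measurement table lacks column(s): %s",
      paste(missing, collapse = ", ")))
  }
  measurements$excluded <- as.logical(measurements$excluded)
  measurements$excluded[is.na(measurements$excluded)] <- FALSE
  measurements
}

# Reshape a measurement table into paired values per subject x tissue x
# metric. Returns a long data.frame (subject_id, tissue, metric, value_1,
# value_2) with unpaired rows recorded in attr(,"unpaired").
pair_measurements <- function(measurements,
                              pairing = c("test_retest", "interobserver"),
                              observer = NULL, scan_selection = NULL,
                              seed = 1L) {
  pairing <- match.arg(pairing)
  meas <- check_measurements(measurements)
  meas <- meas[!meas$excluded, , drop = FALSE]

  if (pairing == "test_retest") {
    if (is.null(observer)) observer <- sort(unique(meas$observer_id))[1]
    sub <- meas[meas$observer_id == observer, , drop = FALSE]
    a <- sub[sub$scan_index == 1, , drop = FALSE]
    b <- sub[sub$scan_index == 2, , drop = FALSE]
  } else {
    obs <- sort(unique(meas$observer_id))
    if (length(obs) < 2L) {
      stop_suv("invalid_measurements",
               "interobserver pairing needs two observers in the table")
    }
    subjects <- sort(unique(meas$subject_id))
    if (is.null(scan_selection)) {
      # the protocol randomizes which scan each subject contributes;
      # reproduce that with a seeded per-subject draw
      scan_selection <- with_seed(seed, {
        stats::setNames(sample(c(1L, 2L), length(subjects), replace = TRUE),
                        subjects)
      })
    }
    sel <- scan_selection[meas$subject_id]
    sub <- meas[!is.na(sel) & meas$scan_index == sel, , drop = FALSE]
    a <- sub[sub$observer_id == obs[1], , drop = FALSE]
    b <- sub[sub$observer_id == obs[2], , drop = FALSE]
  }

  key <- function(df) paste(df$subject_id, df$tissue, sep = "\r")
  ka <- key(a); kb <- key(b)
  common <- intersect(ka, kb)
  unpaired <- rbind(a[!ka %in% common, MEASUREMENT_COLUMNS, drop = FALSE],
                    b[!kb %in% common, MEASUREMENT_COLUMNS, drop = FALSE])
  a <- a[match(common, ka), , drop = FALSE]
  b <- b[match(common, kb), , drop = FALSE]

  out <- do.call(rbind, lapply(suv_metrics(), function(m) {
    data.frame(subject_id = a$subject_id, tissue = a$tissue, metric = m,
               value_1 = a[[m]], value_2 = b[[m]],
               stringsAsFactors = FALSE)
  }))
  attr(out, "unpaired") <- unpaired
  attr(out, "scan_selection") <- if (pairing == "interobserver")
    scan_selection else NULL
  attr(out, "pairing") <- pairing
  out
}

na_summary_row <- function(tissue, metric, n) {
  data.frame(tissue = tissue, metric = metric, n = n,
             mean_diff = NA_real_, sd_diff = NA_real_,
             p_shapiro = NA_real_, p_t_log = NA_real_, p_t_orig = NA_real_,
             p_wilcoxon = NA_real_, wsd_ln = NA_real_, wcv_pct = NA_real_,
             rc_upper_pct = NA_real_, rc_lower_pct = NA_real_,
             rc_upper_ci_lo = NA_real_, rc_upper_ci_hi = NA_real_,
             rc_lower_ci_lo = NA_real_, rc_lower_ci_hi = NA_real_,
             pearson_r_orig = NA_real_, p_pearson_orig = NA_real_,
             pearson_r_log = NA_real_, p_pearson_log = NA_real_,
             kendall_tau_orig = NA_real_, p_kendall_orig = NA_real_,
             kendall_tau_log = NA_real_, p_kendall_log = NA_real_,
             stringsAsFactors = FALSE)
}

summarize_pair <- function(ps) {
  d <- log_differences(ps)
  wsd <- within_subject_sd(d)
  rc <- repeatability_coefficients(d)
  ci <- rc_confidence_intervals(d)
  pt <- paired_tests(ps)
  tr <- if (ps$n >= 3) trend_tests(ps) else NULL
  row <- na_summary_row(ps$tissue, ps$metric, ps$n)
  row$mean_diff <- mean(ps$suv_2 - ps$suv_1)
  row$sd_diff <- stats::sd(ps$suv_2 - ps$suv_1)
  row$p_shapiro <- pt$p_shapiro
  row$p_t_log <- pt$p_t_log
  row$p_t_orig <- pt$p_t_orig
  row$p_wilcoxon <- pt$p_wilcoxon
  row$wsd_ln <- wsd
  row$wcv_pct <- wcv_percent(wsd)
  row$rc_upper_pct <- rc[["upper"]]
  row$rc_lower_pct <- rc[["lower"]]
  row$rc_upper_ci_lo <- ci$upper[1]
  row$rc_upper_ci_hi <- ci$upper[2]
  row$rc_lower_ci_lo <- ci$lower[1]
  row$rc_lower_ci_hi <- ci$lower[2]
  if (!is.null(tr)) {
    row$pearson_r_orig <- tr$pearson_r_orig
    row$p_pearson_orig <- tr$p_pearson_orig
    row$pearson_r_log <- tr$pearson_r_log
    row$p_pearson_log <- tr$p_pearson_log
    row$kendall_tau_orig <- tr$kendall_tau_orig
    row$p_kendall_orig <- tr$p_kendall_orig
    row$kendall_tau_log <- tr$kendall_tau_log
    row$p_kendall_log <- tr$p_kendall_log
  }
  row
}

#' Repeatability / agreement analysis of a measurement cohort
#'
#' Runs the full agreement analysis for every tissue x SUV-metric family:
#' paired differences, Shapiro-Wilk normality of the log differences,
#' paired t (log and original scale) and Wilcoxon signed-rank bias tests,
#' within-subject coefficient of variation, asymmetric repeatability
#' coefficients with chi-square confidence intervals, and trend tests of
#' difference (and absolute difference) against the mean.
#'
#' Two pairings are supported. `"test_retest"` pairs scan 1 against scan 2
#' within a single observer (the first observer present unless `observer`
#' is given). `"interobserver"` pairs the two observers on one scan per
#' subject, chosen by a seeded per-subject random draw (or an explicit
#' `scan_selection`), mirroring protocols where the analysed scan is
#' randomized per patient.
#'
#' Excluded rows never enter the analysis, so `n` can differ across
#' tissues. A tissue x metric family with fewer than 2 complete pairs is
#' reported as a row of `NA` statistics with a warning rather than an
#' error. Rows present for only one member of a pair are dropped and
#' recorded in `attr(, "unpaired")`.
#'
#' @param measurements Data frame (or CSV path) with columns `subject_id`,
#'   `scan_index`, `observer_id`, `tissue`, `suv_max`, `suv_mean`,
#'   `suv_peak`, `excluded`, `exclusion_reason`; alternatively a
#'   pre-paired table with columns `subject_id`, `tissue`, `metric`,
#'   `value_1`, `value_2`.
#' @param pairing `"test_retest"` or `"interobserver"`.
#' @param observer Observer id for the test-retest arm, or `NULL` for the
#'   first observer present.
#' @param scan_selection Named integer vector (subject -> 1 or 2) fixing
#'   which scan the interobserver arm uses per subject.
#' @param seed Seed for the per-subject scan draw when `scan_selection`
#'   is `NULL`.
#' @param alpha Family-wise significance level.
#' @param n_tests `"auto"` (tissues x metrics actually reported) or an
#'   integer override for the Bonferroni family size.
#' @param tissues Tissue ordering for the report; defaults to
#'   [suv_tissues()] followed by any additional labels present.
#' @return A data.frame of class `repeatability_summary`, one row per
#'   tissue x metric, with attributes `pairing`, `alpha`, `n_tests`,
#'   `threshold`, `scan_selection` and `unpaired`.
#' @export
#' @examples
#' cfg <- cohort_config(seed = 7)
#' meas <- generate_cohort(cfg)
#' res <- analyze_cohort(meas, "test_retest")
#' res[res$tissue == "MBP", c("metric", "n", "wcv_pct", "rc_upper_pct")]
analyze_cohort <- function(measurements,
                           pairing = c("test_retest", "interobserver"),
                           observer = NULL, scan_selection = NULL,
                           seed = 1L, alpha = 0.05, n_tests = "auto",
                           tissues = NULL) {
  pairing <- match.arg(pairing)
  if (is.character(measurements) && length(measurements) == 1L) {
    measurements <- read_measurements(measurements)
  }
  prepaired <- all(c("value_1", "value_2", "metric") %in%
                     names(measurements))
  paired <- if (prepaired) {
    measurements
  } else {
    pair_measurements(measurements, pairing, observer, scan_selection,
                      seed)
  }

  if (is.null(tissues)) {
    present <- unique(paired$tissue)
    tissues <- c(intersect(suv_tissues(), present),
                 sort(setdiff(present, suv_tissues())))
  }
  # a metric with no finite values anywhere was never measured (e.g. a
  # reduced simulation panel); skip it rather than warn per tissue
  measured <- unique(paired$metric[is.finite(paired$value_1) |
                                     is.finite(paired$value_2)])
  metrics <- intersect(suv_metrics(), measured)

  rows <- list()
  for (ti in tissues) {
    for (me in metrics) {
      sel <- paired[paired$tissue == ti & paired$metric == me, ,
                    drop = FALSE]
      sel <- sel[is.finite(sel$value_1) & is.finite(sel$value_2), ,
                 drop = FALSE]
      if (nrow(sel) < 2L) {
        warning(sprintf(
          "tissue %s, metric %s: %d complete pair(s); statistics not computed",
          ti, me, nrow(sel)), call. = FALSE)
        rows[[length(rows) + 1L]] <- na_summary_row(ti, me, nrow(sel))
        next
      }
      ps <- paired_sample(sel$value_1, sel$value_2, tissue = ti,
                          metric = me, pairing = pairing,
                          subject_ids = sel$subject_id)
      rows[[length(rows) + 1L]] <- summarize_pair(ps)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  m <- if (identical(n_tests, "auto")) nrow(out) else as.integer(n_tests)
  corr <- bonferroni(alpha, m)
  attr(out, "pairing") <- pairing
  attr(out, "alpha") <- alpha
  attr(out, "n_tests") <- corr$n_tests
  attr(out, "threshold") <- corr$threshold
  attr(out, "scan_selection") <- attr(paired, "scan_selection")
  attr(out, "unpaired") <- attr(paired, "unpaired")
  class(out) <- c("repeatability_summary", "data.frame")
  out
}

#' Bland-Altman data for every tissue x metric family of a cohort
#'
#' @inheritParams analyze_cohort
#' @return List with `points` (long data.frame: `tissue`, `metric`,
#'   `subject_id`, `mean_ln`, `d_ln`) and `limits` (one row per family:
#'   bias, bias CI, upper/lower repeatability limits and their CIs on the
#'   log axis).
#' @export
cohort_bland_altman <- function(measurements,
                                pairing = c("test_retest", "interobserver"),
                                observer = NULL, scan_selection = NULL,
                                seed = 1L) {
  pairing <- match.arg(pairing)
  if (is.character(measurements) && length(measurements) == 1L) {
    measurements <- read_measurements(measurements)
  }
  paired <- pair_measurements(measurements, pairing, observer,
                              scan_selection, seed)
  pts <- list(); lims <- list()
  combos <- unique(paired[, c("tissue", "metric")])
  for (i in seq_len(nrow(combos))) {
    ti <- combos$tissue[i]; me <- combos$metric[i]
    sel <- paired[paired$tissue == ti & paired$metric == me, , drop = FALSE]
    sel <- sel[is.finite(sel$value_1) & is.finite(sel$value_2), ,
               drop = FALSE]
    if (nrow(sel) < 2L) next
    ps <- paired_sample(sel$value_1, sel$value_2, tissue = ti, metric = me,
                        pairing = pairing, subject_ids = sel$subject_id)
    ba <- bland_altman_data(ps)
    pts[[length(pts) + 1L]] <- cbind(tissue = ti, metric = me, ba$points,
                                     stringsAsFactors = FALSE)
    lims[[length(lims) + 1L]] <- data.frame(
      tissue = ti, metric = me, n = ba$n, bias = ba$bias,
      bias_ci_lo = ba$bias_ci[1], bias_ci_hi = ba$bias_ci[2],
      rc_ln_upper = ba$rc_ln[["upper"]], rc_ln_lower = ba$rc_ln[["lower"]],
      rc_ln_upper_ci_lo = ba$rc_ln_ci_upper[1],
      rc_ln_upper_ci_hi = ba$rc_ln_ci_upper[2],
      rc_ln_lower_ci_lo = ba$rc_ln_ci_lower[1],
      rc_ln_lower_ci_hi = ba$rc_ln_ci_lower[2],
      stringsAsFactors = FALSE)
  }
  list(points = do.call(rbind, pts), limits = do.call(rbind, lims))
}

#' Round a repeatability summary for reporting
#'
#' Applies the conventional report formatting: wCV and RC columns to two
#' decimals, P values to three, mean/SD of differences to two.
#'
#' @param summary A [analyze_cohort()] result.
#' @return A plain data.frame with rounded columns.
#' @export
format_summary <- function(summary) {
  out <- as.data.frame(summary)
  two <- c("mean_diff", "sd_diff", "wcv_pct", "rc_upper_pct",
           "rc_lower_pct", "rc_upper_ci_lo", "rc_upper_ci_hi",
           "rc_lower_ci_lo", "rc_lower_ci_hi")
  three <- grep("^p_", names(out), value = TRUE)
  for (cn in two) out[[cn]] <- round(out[[cn]], 2)
  for (cn in three) out[[cn]] <- round(out[[cn]], 3)
  for (cn in c("pearson_r_orig", "pearson_r_log", "kendall_tau_orig",
               "kendall_tau_log", "wsd_ln")) {
    out[[cn]] <- round(out[[cn]], 3)
  }
  out
}

#' @export
print.repeatability_summary <- function(x, ...) {
  cat(sprintf(
    "Repeatability summary (%s): %d tissue x metric families, Bonferroni threshold %g\n",
    attr(x, "pairing"), nrow(x), signif(attr(x, "threshold"), 2)))
  print(format_summary(x)[, c("tissue", "metric", "n", "mean_diff",
                              "sd_diff", "p_wilcoxon", "wcv_pct",
                              "rc_upper_pct", "rc_lower_pct")], ...)
  invisible(x)
}
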
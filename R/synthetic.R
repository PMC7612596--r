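EXCLUSION_REASONS <- c("outside_fov", "artefact", "disease_involvement",
                       "other")

#' Configuration of a synthetic test-retest / interobserver cohort
#'
#' Describes the generative model behind [generate_cohort()]: per
#' tissue x metric, subjects carry a true log-SUV drawn from
#' `Normal(ln(gm_suv), between_sd)`; each scan observes
#' `exp(truth + Normal(0, wSD_ln))` with `wSD_ln = ln(1 + wcv_pct/100)`;
#' observer 2 re-measures observer 1's value times
#' `exp(Normal(0, jitter))`. Exclusions remove whole subject x tissue
#' blocks with a recorded reason, emulating organs outside the field of
#' view or involved by disease.
#'
#' Defaults (22 subjects, organ panel, jitter and exclusion counts) are
#' read from `inst/extdata/default_cohort_config.json`, an illustrative
#' parameter set for a thoracic FDG-PET cohort.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param organs Data frame with columns `tissue`, `metric`, `gm_suv`,
#'   `between_sd`, `wcv_pct`; `NULL` for the shipped default panel.
#' @param observer_jitter Named numeric vector of per-metric log-SDs for
#'   the interobserver re-measurement; `NULL` for defaults.
#' @param exclusions Data frame (or list) with columns `tissue`, and
#'   either `n` (how many subjects to exclude, drawn from the seed) or
#'   `subjects` (explicit indices), plus `reason`; `NULL` for defaults,
#'   `data.frame()` for none.
#' @param seed Integer seed; every random draw in [generate_cohort()]
#'   flows from it.
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(seed = 1)
#' head(cfg$organs, 3)
cohort_config <- function(n_subjects = NULL, organs = NULL,
                          observer_jitter = NULL, exclusions = NULL,
                          seed = 1L) {
  defaults <- jsonlite::read_json(
    system.file("extdata", "default_cohort_config.json",
                package = "suvrepeat"),
    simplifyVector = TRUE)
  if (is.null(n_subjects)) n_subjects <- defaults$n_subjects
  if (is.null(organs)) organs <- defaults$organs
  if (is.null(observer_jitter)) {
    observer_jitter <- unlist(defaults$observer_jitter)
  }
  if (is.null(exclusions)) exclusions <- defaults$exclusions
  organs <- as.data.frame(organs, stringsAsFactors = FALSE)
  exclusions <- as.data.frame(exclusions, stringsAsFactors = FALSE)

  if (!is.numeric(n_subjects) || n_subjects < 2) {
    stop_suv("config", "n_subjects must be >= 2")
  }
  req <- c("tissue", "metric", "gm_suv", "between_sd", "wcv_pct")
  miss <- setdiff(req, names(organs))
  if (length(miss)) {
    stop_suv("config", sprintf("organs table lacks column(s): %s",
                               paste(miss, collapse = ", ")))
  }
  if (any(organs$gm_suv <= 0)) stop_suv("config", "gm_suv must be positive")
  if (any(organs$between_sd < 0)) {
    stop_suv("config", "between_sd must be nonnegative")
  }
  if (any(organs$wcv_pct < 0)) stop_suv("config", "wcv_pct must be nonnegative")
  if (!all(organs$metric %in% suv_metrics())) {
    stop_suv("config", "organs$metric must be one of suv_max/suv_mean/suv_peak")
  }
  if (any(observer_jitter < 0)) {
    stop_suv("config", "observer_jitter must be nonnegative")
  }
  if (nrow(exclusions)) {
    if (!"reason" %in% names(exclusions)) {
      stop_suv("config", "exclusions need a 'reason' column")
    }
    if (!all(exclusions$reason %in% EXCLUSION_REASONS)) {
      stop_suv("config", sprintf("exclusion reason must be one of: %s",
                                 paste(EXCLUSION_REASONS, collapse = ", ")))
    }
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_suv("config", "seed must be a finite integer")
  }
  structure(list(n_subjects = as.integer(n_subjects), organs = organs,
                 observer_jitter = observer_jitter,
                 exclusions = exclusions, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic measurement cohort
#'
#' Draws a full measurement table — every subject, both scans, both
#' observers, all configured tissues and metrics — from the log-normal
#' test-retest model described in [cohort_config()]. The output has the
#' same schema the imaging pipeline emits, so the analysis layer cannot
#' tell simulated and extracted measurements apart.
#'
#' All randomness flows from `config$seed`; the caller's RNG state is
#' left untouched, and the same config yields an identical table.
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `subject_id`, `scan_index`,
#'   `observer_id`, `tissue`, `suv_max`, `suv_mean`, `suv_peak`,
#'   `excluded`, `exclusion_reason`.
#' @export
#' @examples
#' meas <- generate_cohort(cohort_config(seed = 42))
#' table(meas$tissue[!meas$excluded & meas$scan_index == 1 &
#'                   meas$observer_id == 1])
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  subjects <- sprintf("S%02d", seq_len(n))
  tissues <- unique(config$organs$tissue)

  with_seed(config$seed, {
    # subject x tissue exclusion map
    excl_flag <- matrix(FALSE, n, length(tissues),
                        dimnames = list(subjects, tissues))
    excl_reason <- matrix(NA_character_, n, length(tissues),
                          dimnames = list(subjects, tissues))
    if (nrow(config$exclusions)) {
      for (i in seq_len(nrow(config$exclusions))) {
        e <- config$exclusions[i, ]
        if (!e$tissue %in% tissues) {
          stop_suv("config", sprintf("exclusion names unknown tissue '%s'",
                                     e$tissue))
        }
        idx <- if (!is.null(e$subjects) && !all(is.na(e$subjects))) {
          unlist(e$subjects)
        } else {
          sample(n, min(e$n, n))
        }
        excl_flag[idx, e$tissue] <- TRUE
        excl_reason[idx, e$tissue] <- e$reason
      }
    }

    # values[subject, scan, observer] per organ x metric row
    vals <- list()
    for (i in seq_len(nrow(config$organs))) {
      o <- config$organs[i, ]
      wsd <- log(1 + o$wcv_pct / 100)
      jit <- config$observer_jitter[[o$metric]]
      if (is.null(jit)) jit <- 0
      truth <- stats::rnorm(n, log(o$gm_suv), o$between_sd)
      v <- array(NA_real_, c(n, 2, 2))
      for (scan in 1:2) {
        obs1 <- exp(truth + stats::rnorm(n, 0, wsd))
        v[, scan, 1] <- obs1
        v[, scan, 2] <- obs1 * exp(stats::rnorm(n, 0, jit))
      }
      vals[[paste(o$tissue, o$metric, sep = "\r")]] <- v
    }

    grid <- expand.grid(tissue = tissues, observer_id = 1:2,
                        scan_index = 1:2, subject_id = subjects,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[, c("subject_id", "scan_index", "observer_id", "tissue")]
    si <- match(grid$subject_id, subjects)
    metric_col <- function(metric) {
      out <- rep(NA_real_, nrow(grid))
      for (ti in tissues) {
        v <- vals[[paste(ti, metric, sep = "\r")]]
        if (is.null(v)) next
        rows <- which(grid$tissue == ti)
        out[rows] <- v[cbind(si[rows], grid$scan_index[rows],
                             grid$observer_id[rows])]
      }
      out
    }
    grid$suv_max <- metric_col("suv_max")
    grid$suv_mean <- metric_col("suv_mean")
    grid$suv_peak <- metric_col("suv_peak")
    key <- cbind(si, match(grid$tissue, tissues))
    grid$excluded <- excl_flag[key]
    grid$exclusion_reason <- excl_reason[key]
    rownames(grid) <- NULL
    grid
  })
}
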
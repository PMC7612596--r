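#' Read and write measurement tables
#'
#' The measurement CSV is the interchange format between the imaging layer
#' and the analysis layer: one row per subject x scan x observer x tissue
#' with columns `subject_id`, `scan_index`, `observer_id`, `tissue`,
#' `suv_max`, `suv_mean`, `suv_peak`, `excluded`, `exclusion_reason`.
#' Writing is deterministic (fixed column order, no row names), so
#' identical inputs give byte-identical files.
#'
#' @param measurements Measurement data frame.
#' @param path CSV file path.
#' @return `read_measurements()` returns the validated data frame;
#'   `write_measurements()` returns `path` invisibly.
#' @export
write_measurements <- function(measurements, path) {
  measurements <- check_measurements(measurements)
  utils::write.csv(measurements[, MEASUREMENT_COLUMNS], path,
                   row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       tissue = "character"))
  df$exclusion_reason[df$exclusion_reason %in% ""] <- NA_character_
  check_measurements(df)
}

#' Extract a measurement table from volumes and VOI definitions
#'
#' Applies the measurement protocol to a set of acquired (or simulated)
#' scans: converts each volume to SUV, discretizes each VOI, and extracts
#' the SUVmax / SUVmean / SUVpeak triplet. A VOI that contains no voxel
#' centers (outside the field of view) yields an excluded row with reason
#' `outside_fov` instead of an error. When a `liver` mask is supplied,
#' lung ROIs that violate the liver-clearance constraint are flagged as
#' excluded with reason `other`.
#'
#' @param volumes List of [pet_volume()] objects (Bq/mL), one per scan.
#' @param metas List of [scan_meta()] aligned with `volumes`.
#' @param vois List of [sphere_voi()] / [mask_roi()] objects.
#' @param observer_id Observer label for the emitted rows.
#' @param peak_diameter_mm SUVpeak sphere diameter.
#' @param liver Optional liver [mask_roi()] for the lung-distance check.
#' @param lung_min_distance_mm Required lung-to-liver clearance.
#' @return Measurement data frame (schema of [write_measurements()]).
#' @export
extract_measurements <- function(volumes, metas, vois, observer_id = 1L,
                                 peak_diameter_mm = 12, liver = NULL,
                                 lung_min_distance_mm = 20) {
  stopifnot(length(volumes) == length(metas))
  rows <- list()
  for (s in seq_along(volumes)) {
    suv <- activity_to_suv(volumes[[s]], metas[[s]])
    if (suv$n_negative > 0) {
      message(sprintf(
        "subject %s scan %d: %d negative voxel(s) retained in SUV volume",
        metas[[s]]$subject_id, metas[[s]]$scan_index, suv$n_negative))
    }
    for (v in vois) {
      tissue <- v$tissue
      row <- data.frame(subject_id = metas[[s]]$subject_id,
                        scan_index = metas[[s]]$scan_index,
                        observer_id = observer_id, tissue = tissue,
                        suv_max = NA_real_, suv_mean = NA_real_,
                        suv_peak = NA_real_, excluded = FALSE,
                        exclusion_reason = NA_character_,
                        stringsAsFactors = FALSE)
      trip <- tryCatch(
        extract_suv_triplet(suv, v, peak_diameter_mm = peak_diameter_mm),
        suvrepeat_empty_voi = function(e) NULL)
      if (is.null(trip)) {
        row$excluded <- TRUE
        row$exclusion_reason <- "outside_fov"
        message(sprintf("subject %s scan %d: VOI '%s' outside field of view",
                        metas[[s]]$subject_id, metas[[s]]$scan_index, tissue))
      } else {
        row$suv_max <- trip$suv_max
        row$suv_mean <- trip$suv_mean
        row$suv_peak <- trip$suv_peak
        if (!is.null(liver) && grepl("^lung_", tissue)) {
          chk <- validate_lung_roi(v, liver, suv, lung_min_distance_mm)
          if (!chk$pass) {
            row$excluded <- TRUE
            row$exclusion_reason <- "other"
            message(sprintf(
              "subject %s scan %d: lung ROI '%s' only %.1f mm from liver (< %g mm)",
              metas[[s]]$subject_id, metas[[s]]$scan_index, tissue,
              chk$distance_mm, lung_min_distance_mm))
          }
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Simulate a measurement cohort to disk
#'
#' @param out_dir Output directory (created if absent).
#' @param config A [cohort_config()]; `NULL` for the default panel.
#' @param seed Optional seed overriding `config$seed`.
#' @return Path of the written `measurements.csv`, invisibly.
#' @export
run_simulate <- function(out_dir, config = NULL, seed = NULL) {
  if (is.null(config)) config <- cohort_config(seed = if (is.null(seed)) 1L else seed)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meas <- generate_cohort(config)
  write_measurements(meas, file.path(out_dir, "measurements.csv"))
}

#' Extract measurements from a manifest of NIfTI volumes
#'
#' The manifest is a JSON object:
#' `{"voi_file": "vois.json", "subjects": [{"subject_id": "S01",`
#' `"scans": [{"scan_index": 1, "volume": "s01_scan1.nii.gz",`
#' `"weight_kg": 75, "injected_activity_mbq": 300,`
#' `"injection_time_min": 0, "scan_start_min": 67}, ...]}, ...]}`.
#' Relative paths resolve against the manifest's directory.
#'
#' @param manifest Path to the manifest JSON.
#' @param out Path for the output measurement CSV.
#' @param observer_id Observer label for the emitted rows.
#' @param peak_diameter_mm SUVpeak sphere diameter.
#' @return The measurement data frame, invisibly; `out` is written.
#' @export
run_extract <- function(manifest, out, observer_id = 1L,
                        peak_diameter_mm = 12) {
  man <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  base <- dirname(normalizePath(manifest))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p
                         else file.path(base, p)
  vois <- read_voi_json(resolve(man$voi_file))
  vois <- lapply(vois, function(v) {
    if (inherits(v, "mask_voi_ref")) {
      mvol <- read_pet_volume(resolve(v$mask_path))
      mask_roi(mvol$values != 0, v$tissue)
    } else v
  })
  rows <- list()
  for (sub in man$subjects) {
    volumes <- list(); metas <- list()
    for (sc in sub$scans) {
      volumes[[length(volumes) + 1L]] <- read_pet_volume(resolve(sc$volume))
      metas[[length(metas) + 1L]] <- scan_meta(
        sub$subject_id, sc$weight_kg, sc$injected_activity_mbq,
        sc$injection_time_min, sc$scan_start_min, sc$scan_index)
    }
    rows[[length(rows) + 1L]] <- extract_measurements(
      volumes, metas, vois, observer_id = observer_id,
      peak_diameter_mm = peak_diameter_mm)
  }
  meas <- do.call(rbind, rows)
  write_measurements(meas, out)
  invisible(meas)
}

#' Run the agreement analysis and write report tables
#'
#' Produces the test-retest summary (scan 1 vs scan 2 within observer),
#' the interobserver summary (observer 1 vs 2 on a per-subject randomly
#' selected scan), and Bland-Altman plot data for both arms.
#'
#' @param measurements Measurement data frame or CSV path.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param alpha Family-wise significance level.
#' @param n_tests `"auto"` or an integer Bonferroni family size.
#' @param seed Seed for the interobserver per-subject scan draw.
#' @param observer Observer for the test-retest arm (default: first).
#' @return List with `test_retest`, `interobserver` (both
#'   [analyze_cohort()] results, the latter `NULL` when the table has a
#'   single observer) and `bland_altman` (per-arm point/limit tables).
#' @export
run_analyze <- function(measurements, out_dir = NULL, alpha = 0.05,
                        n_tests = "auto", seed = 1L, observer = NULL) {
  if (is.character(measurements) && length(measurements) == 1L) {
    measurements <- read_measurements(measurements)
  }
  tr <- analyze_cohort(measurements, "test_retest", observer = observer,
                       alpha = alpha, n_tests = n_tests)
  ba_tr <- cohort_bland_altman(measurements, "test_retest",
                               observer = observer)
  two_obs <- length(unique(
    measurements$observer_id[!check_measurements(measurements)$excluded])) >= 2
  io <- NULL; ba_io <- NULL
  if (two_obs) {
    io <- analyze_cohort(measurements, "interobserver", seed = seed,
                         alpha = alpha, n_tests = n_tests)
    ba_io <- cohort_bland_altman(measurements, "interobserver", seed = seed)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(format_summary(tr),
                     file.path(out_dir, "test_retest_summary.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(ba_tr$points,
                     file.path(out_dir, "test_retest_bland_altman.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(ba_tr$limits,
                     file.path(out_dir, "test_retest_ba_limits.csv"),
                     row.names = FALSE, na = "")
    if (two_obs) {
      utils::write.csv(format_summary(io),
                       file.path(out_dir, "interobserver_summary.csv"),
                       row.names = FALSE, na = "")
      utils::write.csv(ba_io$points,
                       file.path(out_dir, "interobserver_bland_altman.csv"),
                       row.names = FALSE, na = "")
      utils::write.csv(ba_io$limits,
                       file.path(out_dir, "interobserver_ba_limits.csv"),
                       row.names = FALSE, na = "")
      sel <- attr(io, "scan_selection")
      utils::write.csv(data.frame(subject_id = names(sel),
                                  selected_scan = as.integer(sel)),
                       file.path(out_dir, "interobserver_scan_selection.csv"),
                       row.names = FALSE)
    }
  }
  list(test_retest = tr, interobserver = io,
       bland_altman = list(test_retest = ba_tr, interobserver = ba_io))
}

#' Simulate, analyze and report in one call
#'
#' End-to-end deterministic run: generates a synthetic cohort from `seed`,
#' writes the measurement CSV, runs both analysis arms and writes the
#' report tables into `out_dir`. Identical `seed` and config produce
#' byte-identical outputs.
#'
#' @inheritParams run_analyze
#' @param out_dir Output directory.
#' @param config Optional [cohort_config()].
#' @param seed Seed driving both the simulation and the interobserver
#'   scan draw.
#' @return The [run_analyze()] result, invisibly.
#' @export
run_pipeline <- function(out_dir, config = NULL, seed = 1L, alpha = 0.05,
                         n_tests = "auto") {
  csv <- run_simulate(out_dir, config = config, seed = seed)
  res <- run_analyze(csv, out_dir = out_dir, alpha = alpha,
                     n_tests = n_tests, seed = seed)
  invisible(res)
}
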
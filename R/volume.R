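#' PET activity-concentration volume
#'
#' A 3-D voxel grid of activity concentration with world geometry. Voxel
#' indices are 1-based in R; the world position of voxel `(i, j, k)` is
#' `origin + (c(i, j, k) - 1) * spacing`, i.e. `origin` is the world
#' coordinate (mm) of the *center* of the first voxel. Negative voxel
#' values can occur as reconstruction noise in low-uptake regions; they are
#' counted in `n_negative` and retained, never clamped, because clamping
#' would bias SUVmean in the lung.
#'
#' @param values 3-D numeric array of activity concentration (Bq/mL).
#' @param spacing Per-axis voxel size in mm (length 3, or a scalar recycled).
#' @param origin World coordinate (mm) of the first voxel's center.
#' @param units Unit label, `"Bq/mL"` for raw volumes, `"SUV"` after
#'   normalization.
#' @return An object of class `pet_volume`: a list with elements `values`,
#'   `spacing`, `origin`, `units` and `n_negative`.
#' @seealso [activity_to_suv()], [read_pet_volume()]
#' @export
#' @examples
#' vol <- pet_volume(array(5000, dim = c(10, 10, 10)), spacing = 2)
#' vol$n_negative
pet_volume <- function(values, spacing, origin = c(0, 0, 0),
                       units = "Bq/mL") {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop_suv("invalid_volume", "'values' must be a 3-D array")
  }
  if (!all(is.finite(values))) {
    stop_suv("invalid_volume", "volume contains non-finite voxel values")
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop_suv("invalid_volume", "'spacing' must be 3 positive voxel sizes (mm)")
  }
  if (length(origin) != 3L || !all(is.finite(origin))) {
    stop_suv("invalid_volume", "'origin' must be a finite mm triplet")
  }
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin), units = units,
         n_negative = sum(values < 0)),
    class = if (identical(units, "SUV")) c("suv_volume", "pet_volume")
            else "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, units %s\n",
              class(x)[1L], paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"), x$units))
  cat(sprintf("  range [%.4g, %.4g]", min(x$values), max(x$values)))
  if (x$n_negative > 0) {
    cat(sprintf("  (%d negative voxels retained)", x$n_negative))
  }
  cat("\n")
  invisible(x)
}

# per-axis world coordinates of voxel centers
voxel_axes <- function(volume) {
  d <- dim(volume$values)
  lapply(1:3, function(k) {
    volume$origin[k] + (seq_len(d[k]) - 1) * volume$spacing[k]
  })
}

#' Scan acquisition metadata
#'
#' Holds the quantities needed for body-weight SUV normalization: patient
#' weight, injected activity and the injection-to-scan interval over which
#' the dose decays.
#'
#' @param subject_id Opaque subject identifier.
#' @param weight_kg Patient weight in kg (> 0).
#' @param injected_activity_mbq Injected activity in MBq at injection time
#'   (> 0); the acquisition protocol targets 4 MBq/kg.
#' @param injection_time,scan_start Either numeric minutes on a common
#'   clock, or `POSIXct` timestamps, or ISO-8601 strings. `scan_start` must
#'   not precede `injection_time`.
#' @param scan_index Which scan of the test-retest pair, 1 or 2.
#' @return An object of class `scan_meta`.
#' @export
#' @examples
#' scan_meta("S01", weight_kg = 75, injected_activity_mbq = 300,
#'           injection_time = 0, scan_start = 67)
scan_meta <- function(subject_id, weight_kg, injected_activity_mbq,
                      injection_time, scan_start, scan_index = 1L) {
  if (!is.numeric(weight_kg) || length(weight_kg) != 1L ||
      !is.finite(weight_kg) || weight_kg <= 0) {
    stop_suv("invalid_metadata", "weight_kg must be a positive scalar")
  }
  if (!is.numeric(injected_activity_mbq) ||
      length(injected_activity_mbq) != 1L ||
      !is.finite(injected_activity_mbq) || injected_activity_mbq <= 0) {
    stop_suv("invalid_metadata",
             "injected_activity_mbq must be a positive scalar")
  }
  t0 <- as_minutes(injection_time)
  t1 <- as_minutes(scan_start)
  if (t1 < t0) {
    stop_suv("chronology", sprintf(
      "scan_start precedes injection_time for subject '%s'", subject_id))
  }
  if (!scan_index %in% c(1L, 2L)) {
    stop_suv("invalid_metadata", "scan_index must be 1 or 2")
  }
  structure(
    list(subject_id = as.character(subject_id), weight_kg = weight_kg,
         injected_activity_mbq = injected_activity_mbq,
         injection_time = injection_time, scan_start = scan_start,
         uptake_min = t1 - t0, scan_index = as.integer(scan_index)),
    class = "scan_meta")
}

as_minutes <- function(x) {
  if (inherits(x, "POSIXt")) return(as.numeric(x) / 60)
  if (is.character(x)) {
    p <- as.POSIXct(x, tz = "UTC")
    if (is.na(p)) stop_suv("invalid_metadata",
                           sprintf("unparseable timestamp '%s'", x))
    return(as.numeric(p) / 60)
  }
  if (is.numeric(x) && length(x) == 1L && is.finite(x)) return(x)
  stop_suv("invalid_metadata", "timestamps must be numeric minutes, POSIXct or ISO strings")
}

#' F-18 physical half-life in minutes
#' @export
F18_HALF_LIFE_MIN <- 109.77

#' Convert an activity-concentration volume to body-weight SUV
#'
#' Computes the standard body-weight SUV: voxel activity concentration
#' (Bq/mL) divided by decay-corrected injected activity per gram of body
#' weight, taking 1 g of tissue as 1 mL. The injected dose is decay
#' corrected from injection time to scan start with the F-18 half-life,
#' so `SUV = C / (D * 2^(-t / T_half) / (W * 1000))` with `D` in Bq, `t`
#' the uptake time in minutes and `W` the weight in kg.
#'
#' @param volume A [pet_volume()] in Bq/mL.
#' @param meta A [scan_meta()] for the same acquisition.
#' @param half_life_min Radionuclide half-life in minutes; defaults to
#'   [F18_HALF_LIFE_MIN].
#' @return A `suv_volume` with identical geometry and unitless values.
#' @export
#' @examples
#' vol <- pet_volume(array(5000, dim = c(4, 4, 4)), spacing = 2)
#' m <- scan_meta("S01", 70, 350, injection_time = 0, scan_start = 0)
#' suv <- activity_to_suv(vol, m)
#' range(suv$values)  # 1.0: 350 MBq over 70 kg at 5000 Bq/mL
activity_to_suv <- function(volume, meta, half_life_min = F18_HALF_LIFE_MIN) {
  stopifnot(inherits(volume, "pet_volume"), inherits(meta, "scan_meta"))
  if (identical(volume$units, "SUV")) {
    stop_suv("invalid_volume", "volume is already in SUV units")
  }
  decayed_bq <- meta$injected_activity_mbq * 1e6 *
    2^(-meta$uptake_min / half_life_min)
  factor <- (meta$weight_kg * 1000) / decayed_bq
  out <- pet_volume(volume$values * factor, volume$spacing, volume$origin,
                    units = "SUV")
  out$meta <- meta
  out
}

#' Read / write PET volumes as NIfTI-1
#'
#' `write_pet_volume()` stores the voxel grid with an axis-aligned affine
#' built from `spacing` and `origin`; `read_pet_volume()` inverts that.
#' Reading assumes an axis-aligned transform (no rotation): spacing is
#' taken from `pixdim` and the origin from the translation column of the
#' stored xform.
#'
#' @param volume A [pet_volume()].
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @param units Unit label to attach on read.
#' @return `read_pet_volume()` returns a [pet_volume()];
#'   `write_pet_volume()` returns `path` invisibly.
#' @export
write_pet_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  aff <- diag(c(volume$spacing, 1))
  aff[1:3, 4] <- volume$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_pet_volume
#' @export
read_pet_volume <- function(path, units = "Bq/mL") {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  spacing <- abs(RNifti::pixdim(img))[1:3]
  aff <- RNifti::xform(img)
  pet_volume(vals, spacing = spacing, origin = aff[1:3, 4], units = units)
}
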
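default_compartments <- function() {
  data.frame(
    tissue = c("MBP", "BM", "lung_RUZ"),
    cx = c(40, 86, 63), cy = c(40, 40, 88), cz = c(39, 39, 39),
    rx = c(12, 12, 18), ry = c(12, 12, 16), rz = c(12, 12, 14),
    suv = c(2.0, 1.8, 0.5),
    noise_sd = c(0, 0, 0),
    wcv_pct = c(10, 15, 20),
    stringsAsFactors = FALSE)
}

#' Specification of a paired digital phantom
#'
#' A simple geometric stand-in for a thoracic acquisition: ellipsoidal
#' organ compartments of uniform target SUV on a low-background grid at
#' PET-like 2 mm voxels. A scan pair differs by a per-compartment
#' multiplicative log-normal factor (the test-retest effect) plus optional
#' additive Gaussian voxel noise (a crude stand-in for reconstruction
#' noise). Geometry is deterministic; only the intensities depend on the
#' seed.
#'
#' @param shape Grid dimensions in voxels.
#' @param spacing_mm Voxel size per axis in mm.
#' @param compartments Data frame with columns `tissue`, `cx`, `cy`, `cz`
#'   (center, mm), `rx`, `ry`, `rz` (semi-axes, mm), `suv` (target),
#'   `noise_sd` (additive voxel SD in SUV units) and `wcv_pct` (true
#'   per-compartment test-retest wCV). `NULL` for a 3-compartment default.
#' @param background_suv Background SUV outside all compartments.
#' @param seed Integer seed for the intensity draws.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 40), spacing_mm = c(2, 2, 2),
                         compartments = NULL, background_suv = 0.05,
                         seed = 1L) {
  if (is.null(compartments)) compartments <- default_compartments()
  compartments <- as.data.frame(compartments, stringsAsFactors = FALSE)
  req <- c("tissue", "cx", "cy", "cz", "rx", "ry", "rz", "suv",
           "noise_sd", "wcv_pct")
  miss <- setdiff(req, names(compartments))
  if (length(miss)) {
    stop_suv("config", sprintf("compartments lack column(s): %s",
                               paste(miss, collapse = ", ")))
  }
  if (any(compartments$noise_sd < 0) || any(compartments$wcv_pct < 0)) {
    stop_suv("config", "noise_sd and wcv_pct must be nonnegative")
  }
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  extent <- (shape - 1) * spacing_mm  # voxel centers span [0, extent]
  lo <- cbind(compartments$cx - compartments$rx,
              compartments$cy - compartments$ry,
              compartments$cz - compartments$rz)
  hi <- cbind(compartments$cx + compartments$rx,
              compartments$cy + compartments$ry,
              compartments$cz + compartments$rz)
  if (any(lo < 0) || any(sweep(hi, 2, extent) > 0)) {
    stop_suv("geometry", "a compartment extends outside the phantom grid")
  }
  structure(list(shape = as.integer(shape),
                 spacing_mm = as.numeric(spacing_mm),
                 compartments = compartments,
                 background_suv = background_suv,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a paired digital phantom with metadata and VOI definitions
#'
#' Builds the two activity-concentration volumes of a simulated
#' test-retest pair. Compartment SUV in scan k is
#' `suv * exp(Normal(0, ln(1 + wcv_pct/100)))`, drawn independently per
#' scan and compartment, so the log-difference SD across many simulated
#' subjects is `sqrt(2) * ln(1 + wcv/100)` — the structure the
#' repeatability analysis assumes. SUV is converted to Bq/mL using the
#' returned metadata (75 kg, 300 MBq at 4 MBq/kg, 67 min uptake), so
#' [activity_to_suv()] recovers the target SUV on average.
#'
#' @param spec A [phantom_spec()].
#' @param subject_id Identifier stamped into the metadata.
#' @return List with `volumes` (two [pet_volume()] objects in Bq/mL),
#'   `meta` (two [scan_meta()]), `vois` (15 mm [sphere_voi()] at each
#'   compartment center — seed-independent), `truth` (the compartment
#'   table) and `factors` (the drawn per-scan multiplicative factors).
#' @export
#' @examples
#' spec <- phantom_spec(seed = 3)
#' ph <- generate_phantom_pair(spec)
#' suv1 <- activity_to_suv(ph$volumes[[1]], ph$meta[[1]])
generate_phantom_pair <- function(spec, subject_id = "P01") {
  stopifnot(inherits(spec, "phantom_spec"))
  comp <- spec$compartments
  ncomp <- nrow(comp)

  geom <- pet_volume(array(0, dim = spec$shape), spec$spacing_mm)
  ax <- voxel_axes(geom)
  masks <- lapply(seq_len(ncomp), function(i) {
    q <- outer(outer(((ax[[1]] - comp$cx[i]) / comp$rx[i])^2,
                     ((ax[[2]] - comp$cy[i]) / comp$ry[i])^2, `+`),
               ((ax[[3]] - comp$cz[i]) / comp$rz[i])^2, `+`)
    q <= 1
  })

  meta <- lapply(1:2, function(k) {
    scan_meta(subject_id, weight_kg = 75, injected_activity_mbq = 300,
              injection_time = 0, scan_start = 67, scan_index = k)
  })
  # Bq/mL per unit SUV for this metadata
  suv_to_bqml <- meta[[1]]$injected_activity_mbq * 1e6 *
    2^(-meta[[1]]$uptake_min / F18_HALF_LIFE_MIN) /
    (meta[[1]]$weight_kg * 1000)

  wsd <- log(1 + comp$wcv_pct / 100)
  out <- with_seed(spec$seed, {
    factors <- matrix(exp(stats::rnorm(2 * ncomp, 0, rep(wsd, 2))),
                      nrow = ncomp, ncol = 2,
                      dimnames = list(comp$tissue, NULL))
    volumes <- lapply(1:2, function(k) {
      suv <- array(spec$background_suv, dim = spec$shape)
      for (i in seq_len(ncomp)) {
        m <- masks[[i]]
        suv[m] <- comp$suv[i] * factors[i, k]
        if (comp$noise_sd[i] > 0) {
          suv[m] <- suv[m] + stats::rnorm(sum(m), 0, comp$noise_sd[i])
        }
      }
      pet_volume(suv * suv_to_bqml, spec$spacing_mm)
    })
    list(volumes = volumes, factors = factors)
  })

  vois <- lapply(seq_len(ncomp), function(i) {
    sphere_voi(comp$tissue[i], c(comp$cx[i], comp$cy[i], comp$cz[i]),
               diameter_mm = 15)
  })
  list(volumes = out$volumes, meta = meta, vois = vois, truth = comp,
       factors = out$factors)
}
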
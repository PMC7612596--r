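#' Spherical volume of interest
#'
#' The measurement protocol samples most tissues with a 1.5 cm diameter
#' sphere (descending aorta for the mediastinal blood pool, lateral LV
#' wall, mid-vertebral bone marrow, teres major muscles); lung zones use a
#' drawn voxel mask instead (see [mask_roi()]).
#'
#' @param tissue Tissue label, normally one of [suv_tissues()].
#' @param center_mm World coordinate (mm) of the sphere center.
#' @param diameter_mm Sphere diameter in mm; protocol default 15.
#' @return An object of class `sphere_voi`.
#' @export
sphere_voi <- function(tissue, center_mm, diameter_mm = 15) {
  if (!is.numeric(center_mm) || length(center_mm) != 3L ||
      !all(is.finite(center_mm))) {
    stop_suv("invalid_voi", "center_mm must be a finite mm triplet")
  }
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1L ||
      !is.finite(diameter_mm) || diameter_mm <= 0) {
    stop_suv("invalid_voi", "diameter_mm must be positive")
  }
  structure(list(tissue = as.character(tissue),
                 center_mm = as.numeric(center_mm),
                 diameter_mm = diameter_mm),
            class = "sphere_voi")
}

#' Voxel-mask region of interest
#'
#' @param mask Logical 3-D array congruent with the volume it indexes; at
#'   least one voxel must be set.
#' @param tissue Tissue label.
#' @return An object of class `mask_roi`.
#' @export
mask_roi <- function(mask, tissue) {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stop_suv("invalid_voi", "mask must be a 3-D array")
  }
  mask <- mask != 0
  if (!any(mask)) {
    stop_suv("empty_voi", sprintf("mask for tissue '%s' selects no voxels",
                                  as.character(tissue)))
  }
  structure(list(mask = mask, tissue = as.character(tissue)),
            class = "mask_roi")
}

#' Discretize a spherical VOI onto a voxel grid
#'
#' A voxel belongs to the sphere iff its *center* lies within
#' `diameter_mm / 2` of the sphere center (center-inclusion rule; no
#' partial-volume weighting). On a uniform grid this makes the mask
#' translation-equivariant under whole-voxel shifts.
#'
#' @param voi A [sphere_voi()].
#' @param volume A [pet_volume()] supplying the grid geometry.
#' @return A [mask_roi()] congruent with `volume`.
#' @export
#' @examples
#' vol <- pet_volume(array(0, dim = c(20, 20, 20)), spacing = 2)
#' roi <- voxelize_sphere(sphere_voi("MBP", c(19, 19, 19), 15), vol)
#' sum(roi$mask)
voxelize_sphere <- function(voi, volume) {
  stopifnot(inherits(voi, "sphere_voi"), inherits(volume, "pet_volume"))
  ax <- voxel_axes(volume)
  r2 <- (voi$diameter_mm / 2)^2
  dx2 <- (ax[[1]] - voi$center_mm[1])^2
  dy2 <- (ax[[2]] - voi$center_mm[2])^2
  dz2 <- (ax[[3]] - voi$center_mm[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  mask <- d2 <= r2
  if (!any(mask)) {
    stop_suv("empty_voi", sprintf(
      "sphere VOI '%s' (d = %g mm at [%s] mm) contains no voxel centers",
      voi$tissue, voi$diameter_mm,
      paste(format(voi$center_mm), collapse = ", ")))
  }
  mask_roi(mask, voi$tissue)
}

# integer index offsets whose world displacement is within radius_mm
sphere_offsets <- function(spacing, radius_mm) {
  reach <- floor(radius_mm / spacing)
  g <- expand.grid(i = -reach[1]:reach[1], j = -reach[2]:reach[2],
                   k = -reach[3]:reach[3])
  d2 <- (g$i * spacing[1])^2 + (g$j * spacing[2])^2 + (g$k * spacing[3])^2
  as.matrix(g[d2 <= radius_mm^2, , drop = FALSE])
}

resolve_region <- function(region, volume) {
  if (inherits(region, "sphere_voi")) region <- voxelize_sphere(region, volume)
  if (is.array(region) && is.logical(region)) {
    region <- mask_roi(region, tissue = NA_character_)
  }
  if (!inherits(region, "mask_roi")) {
    stop_suv("invalid_voi",
             "region must be a mask_roi, a logical array or a sphere_voi")
  }
  if (!identical(dim(region$mask), dim(volume$values))) {
    stop_suv("invalid_voi", "region mask is not congruent with the volume")
  }
  region
}

#' Extract SUVmax, SUVmean and SUVpeak from a region
#'
#' SUVmax is the maximum voxel value in the region and SUVmean the
#' arithmetic mean. SUVpeak is the maximum, over candidate sphere
#' placements centered at each region voxel, of the mean SUV inside a
#' `peak_diameter_mm` sphere (default 12 mm, about 1 cm^3 — the common
#' clinical convention). The peak sphere may extend beyond the region but
#' not beyond the volume: placements whose sphere would protrude outside
#' the grid are skipped.
#'
#' @param suv A `suv_volume` (see [activity_to_suv()]).
#' @param region A [mask_roi()], logical array, or [sphere_voi()].
#' @param peak_diameter_mm Diameter of the SUVpeak sphere in mm.
#' @return An object of class `suv_triplet`: list with `suv_max`,
#'   `suv_mean`, `suv_peak`, `n_voxels` (voxels contributing to the mean)
#'   and `n_peak_placements` (candidate placements that fit in the volume).
#' @export
#' @examples
#' vol <- pet_volume(array(2, dim = c(16, 16, 16)), spacing = 2, units = "SUV")
#' trip <- extract_suv_triplet(vol, sphere_voi("BM", c(15, 15, 15), 15))
#' unlist(trip[c("suv_max", "suv_mean", "suv_peak")])
extract_suv_triplet <- function(suv, region, peak_diameter_mm = 12) {
  stopifnot(inherits(suv, "pet_volume"))
  region <- resolve_region(region, suv)
  idx <- which(region$mask, arr.ind = TRUE)
  vals <- suv$values[region$mask]
  n <- nrow(idx)

  off <- sphere_offsets(suv$spacing, peak_diameter_mm / 2)
  if (nrow(off) == 0L) {
    stop_suv("degenerate_peak", sprintf(
      "peak sphere of %g mm contains no voxels at %s mm spacing",
      peak_diameter_mm, paste(format(suv$spacing), collapse = "x")))
  }
  d <- dim(suv$values)
  sums <- numeric(n)
  valid <- rep(TRUE, n)
  for (r in seq_len(nrow(off))) {
    px <- idx[, 1] + off[r, 1]
    py <- idx[, 2] + off[r, 2]
    pz <- idx[, 3] + off[r, 3]
    inb <- px >= 1L & px <= d[1] & py >= 1L & py <= d[2] &
      pz >= 1L & pz <= d[3]
    valid <- valid & inb
    ok <- which(inb)
    if (length(ok)) {
      sums[ok] <- sums[ok] + suv$values[cbind(px[ok], py[ok], pz[ok])]
    }
  }
  if (!any(valid)) {
    stop_suv("degenerate_peak",
             "no peak-sphere placement fits inside the volume")
  }
  structure(
    list(suv_max = max(vals), suv_mean = mean(vals),
         suv_peak = max(sums[valid]) / nrow(off),
         n_voxels = n, n_peak_placements = sum(valid),
         tissue = region$tissue),
    class = "suv_triplet")
}

#' Check the liver-distance constraint for a lung ROI
#'
#' Lower-lung ROIs are required to sit at least `min_distance_mm` (default
#' 20 mm) away from the liver to avoid spill-in from hepatic uptake. The
#' distance is the minimum voxel-center-to-voxel-center distance between
#' the two masks.
#'
#' @param region,liver_mask Congruent [mask_roi()] objects (or logical
#'   arrays) on `volume`'s grid.
#' @param volume A [pet_volume()] supplying geometry.
#' @param min_distance_mm Required clearance in mm.
#' @return List with `pass` (logical), `distance_mm`, and `vacuous` (`TRUE`
#'   when the liver mask is empty, in which case the constraint passes with
#'   infinite distance and should be reviewed).
#' @export
validate_lung_roi <- function(region, liver_mask, volume,
                              min_distance_mm = 20) {
  region <- resolve_region(region, volume)
  liver_empty <- if (is.array(liver_mask)) !any(liver_mask != 0)
                 else !any(liver_mask$mask)
  if (liver_empty) {
    return(list(pass = TRUE, distance_mm = Inf, vacuous = TRUE))
  }
  liver_mask <- resolve_region(liver_mask, volume)
  a <- which(region$mask, arr.ind = TRUE)
  b <- which(liver_mask$mask, arr.ind = TRUE)
  sp <- volume$spacing
  aw <- sweep(a - 1, 2, sp, `*`)
  bw <- sweep(b - 1, 2, sp, `*`)
  # min over all pairs; loop over the smaller set, vectorized on the other
  if (nrow(aw) > nrow(bw)) { tmp <- aw; aw <- bw; bw <- tmp }
  best <- Inf
  for (i in seq_len(nrow(aw))) {
    d2 <- (bw[, 1] - aw[i, 1])^2 + (bw[, 2] - aw[i, 2])^2 +
      (bw[, 3] - aw[i, 3])^2
    best <- min(best, min(d2))
  }
  dist <- sqrt(best)
  list(pass = dist >= min_distance_mm, distance_mm = dist, vacuous = FALSE)
}

#' Read and write VOI definitions as JSON
#'
#' The interchange format is a JSON array of objects with fields
#' `tissue_label`, `kind` (`"sphere"` or `"mask"`), and either `center_mm`
#' + `diameter_mm` (sphere) or `mask_path` (mask, a NIfTI file of 0/1
#' voxels).
#'
#' @param vois A list of [sphere_voi()] objects (mask VOIs are referenced
#'   by path and loaded lazily at extraction time).
#' @param path JSON file path.
#' @return `read_voi_json()` returns a list of `sphere_voi` objects and
#'   `list(tissue =, mask_path =)` stubs for mask entries.
#' @export
write_voi_json <- function(vois, path) {
  entries <- lapply(vois, function(v) {
    if (inherits(v, "sphere_voi")) {
      list(tissue_label = v$tissue, kind = "sphere",
           center_mm = v$center_mm, diameter_mm = v$diameter_mm)
    } else {
      list(tissue_label = v$tissue, kind = "mask", mask_path = v$mask_path)
    }
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_voi_json
#' @export
read_voi_json <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(entries, function(e) {
    if (identical(e$kind, "sphere")) {
      sphere_voi(e$tissue_label, unlist(e$center_mm), e$diameter_mm)
    } else if (identical(e$kind, "mask")) {
      structure(list(tissue = e$tissue_label, mask_path = e$mask_path),
                class = "mask_voi_ref")
    } else {
      stop_suv("invalid_voi",
               sprintf("unknown VOI kind '%s'", as.character(e$kind)))
    }
  })
}
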
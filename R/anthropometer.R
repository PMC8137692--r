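#' Tissue mass from a voxel count
#'
#' `mass (g) = N * V_voxel * rho`, where `N` is the voxel count, `V_voxel`
#' the voxel volume in ml and `rho` the tissue density in g/ml (1.06 for
#' muscle, 0.923 for fat).
#'
#' @param n_voxels Non-negative voxel count.
#' @param voxel_volume Voxel volume in ml.
#' @param density Tissue density in g/ml.
#' @return Mass in grams.
#' @export
compute_mass <- function(n_voxels, voxel_volume, density) {
  if (any(n_voxels < 0) || any(voxel_volume < 0) || any(density < 0))
    stop("voxel count, voxel volume and density must be non-negative")
  n_voxels * voxel_volume * density
}

#' Calibrate field-of-view extrapolation factors
#'
#' A clinical scan covers the body from the ischia to the eyes; tissue
#' outside that window is estimated with extrapolation factors: for each
#' tissue of interest (muscle, fat), the ratio of whole-body voxels to
#' voxels inside the window, averaged over a set of whole-body reference
#' volumes. `k >= 1` always, since the window is a subset of the body.
#'
#' Each calibration volume is segmented with its own mask set and the
#' muscle / fat (visceral + subcutaneous) voxel counts are taken whole-body
#' and within its `eyes:ischia` slice range.
#'
#' @param volumes A list of whole-body `labeled_volume`s, each with `eyes`
#'   and `ischia` landmarks and `masks`.
#' @return Object of class `extrapolation_factors`: `k_muscle`, `k_fat`,
#'   `n_volumes`, and the per-volume ratios.
#' @export
calibrate_k <- function(volumes) {
  if (inherits(volumes, "labeled_volume")) volumes <- list(volumes)
  stopifnot(length(volumes) >= 1)
  ratios <- vapply(volumes, function(vol) {
    lm <- vol$landmarks
    if (is.na(lm["eyes"]) || is.na(lm["ischia"]))
      stop("calibration volume lacks eyes/ischia landmarks")
    map <- classify_voxels(vol, vol$masks)
    fov <- c(lm[["eyes"]], lm[["ischia"]])
    m_in <- count_voxels(map, "muscle", within = fov)
    f_in <- count_voxels(map, "fat", within = fov)
    if (m_in == 0 || f_in == 0)
      stop("no muscle or fat voxels inside the acquisition window; ",
           "cannot form an extrapolation ratio")
    c(muscle = count_voxels(map, "muscle") / m_in,
      fat = count_voxels(map, "fat") / f_in)
  }, numeric(2))
  structure(list(k_muscle = mean(ratios["muscle", ]),
                 k_fat = mean(ratios["fat", ]),
                 n_volumes = length(volumes),
                 ratios = ratios),
            class = "extrapolation_factors")
}

#' Assemble extrapolation factors from known values
#'
#' @param k_muscle,k_fat Dimensionless factors, both `>= 1` and finite.
#' @param n_volumes Number of reference volumes they were derived from.
#' @return An `extrapolation_factors` object.
#' @export
extrapolation_factors <- function(k_muscle, k_fat, n_volumes = NA_integer_) {
  if (!is.finite(k_muscle) || !is.finite(k_fat) ||
      k_muscle < 1 || k_fat < 1)
    stop("extrapolation factors must be finite and >= 1")
  structure(list(k_muscle = k_muscle, k_fat = k_fat,
                 n_volumes = n_volumes, ratios = NULL),
            class = "extrapolation_factors")
}

#' Multi-slice body composition with field-of-view extrapolation
#'
#' Converts tissue voxel counts of an acquisition-window tissue map into
#' whole-body mass estimates: muscle body mass `MBM = N_muscle * V_voxel *
#' 1.06 * k_muscle`; fat body mass `FBM = (N_vfat + N_scfat) * V_voxel *
#' 0.923 * k_fat`; visceral fat mass `VFM` is left unextrapolated (the
#' abdominal cavity lies inside the acquisition window) and subcutaneous
#' fat mass is the remainder `SCFM = FBM - VFM`, so `FBM = VFM + SCFM`
#' holds exactly. Lean body mass `LBM` counts in-body voxels with
#' HU >= -29 (non-fat, non-air) at muscle density, extrapolated with
#' `k_muscle`. All masses are reported in kg and, normalized by height
#' squared, as indices in kg/m^2.
#'
#' @param map A `tissue_map` restricted to the acquisition window
#'   (eyes to ischia), e.g. from [acquisition_window()] + [classify_voxels()].
#' @param masks The [mask_set()] the map was classified with (shape checked).
#' @param k [extrapolation_factors()]; use `extrapolation_factors(1, 1)`
#'   for a whole-body volume.
#' @param height Patient height in metres.
#' @return Object of class `body_composition`: `masses_kg` and
#'   `indices_kgm2`, each named `MBM`, `FBM`, `LBM`, `VFM`, `SCFM`;
#'   plus `height_m` and `k`.
#' @export
compute_body_composition <- function(map, masks, k, height) {
  stopifnot(inherits(map, "tissue_map"),
            inherits(k, "extrapolation_factors"), height > 0)
  if (missing(masks) || is.null(masks)) stop("mask set is required")
  stopifnot(inherits(masks, "mask_set"))
  if (!identical(dim(map$class), dim(masks$body)))
    stop("mask shape does not match the tissue map")
  vv <- voxel_volume_ml(map)
  dens <- ct_constants$density
  mbm <- compute_mass(count_voxels(map, "muscle"), vv, dens[["muscle"]]) *
    k$k_muscle
  vfm <- compute_mass(count_voxels(map, "visceral_fat"), vv, dens[["fat"]])
  fat_in_fov <- compute_mass(count_voxels(map, "fat"), vv, dens[["fat"]])
  scfm <- fat_in_fov * k$k_fat - vfm
  lbm <- compute_mass(count_voxels(map, "lean"), vv, dens[["muscle"]]) *
    k$k_muscle
  # FBM is assembled as VFM + SCFM at each reported level so the
  # conservation identity holds to the last bit
  masses <- c(MBM = mbm, FBM = NA, LBM = lbm, VFM = vfm, SCFM = scfm) / 1000
  masses[["FBM"]] <- masses[["VFM"]] + masses[["SCFM"]]
  indices <- masses / height^2
  indices[["FBM"]] <- indices[["VFM"]] + indices[["SCFM"]]
  structure(list(masses_kg = masses,
                 indices_kgm2 = indices,
                 height_m = height, k = k),
            class = "body_composition")
}

#' @export
print.extrapolation_factors <- function(x, ...) {
  cat(sprintf("extrapolation factors (from %s reference volume(s)):\n",
              x$n_volumes))
  cat(sprintf("  k_muscle = %.4f   k_fat = %.4f\n", x$k_muscle, x$k_fat))
  invisible(x)
}

#' @export
print.body_composition <- function(x, ...) {
  cat("whole-body composition estimates:\n")
  tab <- rbind(`mass (kg)` = x$masses_kg,
               `index (kg/m^2)` = x$indices_kgm2)
  print(round(tab, 3))
  invisible(x)
}
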
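#' Single-slice body composition at the third lumbar vertebra
#'
#' Measures cross-sectional tissue areas at L3, the conventional single-slice
#' landmark for whole-body composition surrogacy: skeletal muscle area
#' (psoas, paraspinal and abdominal-wall muscles), visceral fat area and
#' subcutaneous fat area are computed on two adjacent axial slices and the
#' mean of the two is reported. Muscle area is normalized by height squared
#' to the skeletal muscle index (SMI, cm^2/m^2) and classified against the
#' sex-specific low-muscle-mass cut-offs (52.4 for men, 38.5 for women).
#'
#' @param map A `tissue_map` from [classify_voxels()].
#' @param l3_index 1-based slice index of the L3 level; if `NULL`, the `l3`
#'   landmark carried by the map is used.
#' @param height Patient height in metres.
#' @param sex `"male"` or `"female"`.
#' @param neighbor Which adjacent slice forms the pair: `"caudal"` (L3 and
#'   L3+1, the default) or `"cranial"` (L3-1 and L3).
#' @return An object of class `l3_measurements`: `SMA_L3`, `VFA_L3`,
#'   `SCFA_L3` in cm^2 (two-slice means), `SMI` in cm^2/m^2,
#'   `low_muscle_mass` (logical), `sex`, `height_m`, `slices` used.
#' @examples
#' vol <- generate_phantom(phantom_spec(n_slices = 24, grid = c(32, 32),
#'   spacing = c(4, 8, 8), landmarks = c(eyes = 4, l3 = 12, ischia = 20)))
#' measure_l3(classify_voxels(vol, vol$masks), height = 1.75, sex = "male")
#' @export
measure_l3 <- function(map, l3_index = NULL, height, sex,
                       neighbor = c("caudal", "cranial")) {
  stopifnot(inherits(map, "tissue_map"), height > 0)
  neighbor <- match.arg(neighbor)
  if (is.null(l3_index)) {
    l3_index <- map$landmarks[["l3"]]
    if (is.null(l3_index) || is.na(l3_index))
      stop("no L3 slice index supplied and no 'l3' landmark on the map")
  }
  nz <- dim(map$class)[1]
  slices <- if (neighbor == "caudal") c(l3_index, l3_index + 1L)
            else c(l3_index - 1L, l3_index)
  if (any(slices < 1L) || any(slices > nz))
    stop("L3 slice pair ", paste(slices, collapse = ","),
         " outside the volume (", nz, " slices); no adjacent slice available")
  two_slice_mean <- function(cls)
    mean(c(slice_area_cm2(map, cls, slices[1]),
           slice_area_cm2(map, cls, slices[2])))
  sma <- two_slice_mean("muscle")
  smi <- sma / height^2
  structure(list(SMA_L3 = sma,
                 VFA_L3 = two_slice_mean("visceral_fat"),
                 SCFA_L3 = two_slice_mean("subcutaneous_fat"),
                 SMI = smi,
                 low_muscle_mass = classify_low_muscle(smi, sex),
                 sex = sex, height_m = height, slices = slices),
            class = "l3_measurements")
}

#' Low skeletal muscle mass (sarcopenia) classification from SMI
#'
#' Applies the sex-specific skeletal-muscle-index cut-offs of Prado et al.:
#' low muscle mass is SMI strictly below 52.4 cm^2/m^2 for men and strictly
#' below 38.5 cm^2/m^2 for women. A patient exactly at the cut-off is not
#' classified as low.
#'
#' @param smi Skeletal muscle index, cm^2/m^2 (vectorized).
#' @param sex `"male"`/`"female"` (recycled against `smi`).
#' @param cutoffs Named numeric cut-offs, default `c(male = 52.4,
#'   female = 38.5)`.
#' @return Logical vector: `TRUE` = low skeletal muscle mass.
#' @export
classify_low_muscle <- function(smi, sex,
                                cutoffs = c(male = 52.4, female = 38.5)) {
  stopifnot(all(smi >= 0 | is.na(smi)))
  if (!all(sex %in% names(cutoffs)))
    stop("unknown sex code: ", paste(setdiff(sex, names(cutoffs)),
                                     collapse = ", "))
  unname(smi < cutoffs[sex])
}

#' @export
print.l3_measurements <- function(x, ...) {
  cat(sprintf("L3 measurements (slices %d+%d, mean of two):\n",
              x$slices[1], x$slices[2]))
  cat(sprintf("  SMA  %.1f cm^2   VFA %.1f cm^2   SCFA %.1f cm^2\n",
              x$SMA_L3, x$VFA_L3, x$SCFA_L3))
  cat(sprintf("  SMI  %.2f cm^2/m^2 (%s) -> %s\n", x$SMI, x$sex,
              if (x$low_muscle_mass) "LOW skeletal muscle mass"
              else "not low"))
  invisible(x)
}
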
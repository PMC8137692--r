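#' Write a labeled volume to NIfTI with JSON sidecar
#'
#' HU values are written as signed 16-bit NIfTI with voxel spacing in the
#' header. Ground-truth labels (if present) go to a sibling
#' `<base>_labels.nii.gz`, the three masks to `<base>_masks.nii.gz`
#' (bit-packed: 1 = body, 2 = cavity, 4 = muscle compartment), and
#' landmarks, truth masses, height and sex to a `<base>.json` sidecar.
#'
#' @param vol A `labeled_volume`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "labeled_volume"))
  base <- sub("\\.nii(\\.gz)?$", "", path)
  write_nifti_int(vol$hu, vol$spacing, path)
  if (!is.null(vol$labels))
    write_nifti_int(vol$labels, vol$spacing,
                    paste0(base, "_labels.nii.gz"))
  if (!is.null(vol$masks)) {
    m <- vol$masks
    packed <- array(0L, dim(m$body))
    packed <- packed + m$body + 2L * m$cavity + 4L * m$muscle_compartment
    write_nifti_int(packed, vol$spacing, paste0(base, "_masks.nii.gz"))
  }
  sidecar <- list(landmarks = as.list(vol$landmarks),
                  truth_masses_g = as.list(vol$truth_masses),
                  height_m = vol$height_m, sex = vol$sex,
                  spacing_mm = vol$spacing)
  jsonlite::write_json(sidecar, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

write_nifti_int <- function(arr, spacing, path) {
  img <- RNifti::asNifti(
    arr, reference = list(pixdim = c(-1, spacing, 0, 0, 0, 0),
                          datatype = 4L))  # 4 = NIFTI_TYPE_INT16
  RNifti::writeNifti(img, path)
}

#' Read a CT volume from NIfTI (with optional sidecars)
#'
#' Reads HU as integers and spacing from the header; merges landmarks,
#' height, sex and truth masses from a `<base>.json` sidecar, ground-truth
#' labels from `<base>_labels.nii.gz` and masks from `<base>_masks.nii.gz`
#' when those files exist. Values outside a plausible CT range
#' (-1100 to 4000 HU) are rejected with a descriptive error.
#'
#' @param path Path to the HU NIfTI file.
#' @return A `labeled_volume`; components absent on disk are `NULL`
#'   (downstream operations that need them fail with a clear message).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- RNifti::readNifti(path)
  hu <- array(as.integer(round(img)), dim = dim(img))
  if (min(hu) < -1100 || max(hu) > 4000)
    stop("value range [", min(hu), ", ", max(hu),
         "] is not a plausible CT HU range (-1100 to 4000)")
  spacing <- RNifti::pixdim(img)[1:3]
  base <- sub("\\.nii(\\.gz)?$", "", path)

  landmarks <- NULL; height <- NULL; sex <- NULL; masses <- NULL
  sidecar_path <- paste0(base, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!is.null(sc$landmarks))
      landmarks <- vapply(sc$landmarks, as.integer, integer(1))
    height <- sc$height_m; sex <- sc$sex
    if (!is.null(sc$truth_masses_g))
      masses <- vapply(sc$truth_masses_g, as.numeric, numeric(1))
  }
  labels <- NULL
  lab_path <- paste0(base, "_labels.nii.gz")
  if (file.exists(lab_path)) {
    li <- RNifti::readNifti(lab_path)
    labels <- array(as.integer(round(li)), dim = dim(li))
  }
  masks <- NULL
  mask_path <- paste0(base, "_masks.nii.gz")
  if (file.exists(mask_path)) {
    mi <- RNifti::readNifti(mask_path)
    packed <- array(as.integer(round(mi)), dim = dim(mi))
    unpack <- function(bit) array(bitwAnd(packed, bit) > 0L, dim(packed))
    masks <- mask_set(body = unpack(1L), cavity = unpack(2L),
                      muscle_compartment = unpack(4L))
  }
  structure(list(hu = hu, labels = labels, spacing = as.numeric(spacing),
                 landmarks = landmarks, masks = masks,
                 truth_masses = masses, height_m = height, sex = sex),
            class = "labeled_volume")
}

#' Write a cohort table to CSV
#'
#' @param cohort Cohort `data.frame` (one row per patient; missing values
#'   become empty cells).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Expects one row per patient with at least an `id` column; empty cells
#' are missing values (kept as `NA`, rows are not dropped at load).
#' Duplicated ids and negative follow-up times are errors; a height column
#' with median above 3 triggers a warning (heights are expected in metres,
#' not centimetres).
#'
#' @param path CSV path.
#' @return A `data.frame`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such cohort file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if ("id" %in% names(df) && anyDuplicated(df$id))
    stop("duplicated patient ids in cohort file")
  for (tc in intersect(c("time_months", "progression_time_months"),
                       names(df)))
    if (any(df[[tc]] < 0, na.rm = TRUE))
      stop("negative follow-up times in column ", tc)
  hc <- intersect(c("height_m", "height"), names(df))
  if (length(hc) && median(df[[hc[1]]], na.rm = TRUE) > 3)
    warning("height column median > 3: heights appear to be in cm, not m")
  df
}

#' Save / load extrapolation factors as JSON
#'
#' @param k An `extrapolation_factors` object.
#' @param path JSON path.
#' @return `path` (save) or an `extrapolation_factors` object (load).
#' @export
save_extrapolation_factors <- function(k, path) {
  stopifnot(inherits(k, "extrapolation_factors"))
  jsonlite::write_json(list(k_muscle = k$k_muscle, k_fat = k$k_fat,
                            n_volumes = k$n_volumes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_extrapolation_factors
#' @export
load_extrapolation_factors <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- extrapolation_factors(x$k_muscle, x$k_fat)
  k$n_volumes <- x$n_volumes
  k
}
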
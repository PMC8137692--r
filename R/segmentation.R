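#' Construct a mask set (body shape, abdominal cavity, muscle compartment)
#'
#' Multi-slice body-composition measurement classifies HU voxels inside
#' three anatomical masks covering the acquisition window: the body shape,
#' the abdominal cavity, and the muscle compartment. In clinical use these
#' come from multi-atlas segmentation; here they come from phantom geometry
#' or user-supplied mask volumes.
#'
#' @param body,cavity,muscle_compartment Logical 3-D arrays of identical
#'   shape; `cavity` and `muscle_compartment` must be subsets of `body`.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(body, cavity, muscle_compartment) {
  stopifnot(is.logical(body), is.logical(cavity),
            is.logical(muscle_compartment),
            identical(dim(body), dim(cavity)),
            identical(dim(body), dim(muscle_compartment)))
  if (any(cavity & !body)) stop("cavity mask extends outside the body mask")
  if (any(muscle_compartment & !body))
    stop("muscle compartment mask extends outside the body mask")
  structure(list(body = body, cavity = cavity,
                 muscle_compartment = muscle_compartment),
            class = "mask_set")
}

#' Derive a body-shape mask from HU values
#'
#' Seeds the mask with voxels above -400 HU (well above air, below all soft
#' tissue and fat), fills internal holes per axial slice so that internal
#' air (lungs, bowel gas) is included, and keeps the largest connected
#' component of each slice. Processing is per axial slice, which is adequate
#' for torso CT where the body is the largest object in every slice.
#'
#' @param vol A `labeled_volume` (only its `hu` array is used).
#' @param hu_threshold Seed threshold, default -400 HU.
#' @return Logical array of the same shape as `vol$hu`.
#' @export
derive_body_mask <- function(vol, hu_threshold = -400) {
  hu <- if (is.list(vol)) vol$hu else vol
  seed <- hu > hu_threshold
  if (!any(seed)) stop("empty body mask: no voxels above ", hu_threshold, " HU")
  # EBImage operates on stacks of 2-D frames along the 3rd dimension;
  # our arrays are slice-first, so permute to (y, x, slice) and back.
  stack <- aperm(seed, c(2, 3, 1))
  filled <- EBImage::fillHull(stack)
  lab <- EBImage::bwlabel(filled)
  nz <- dim(lab)[3]
  for (i in seq_len(nz)) {
    sl <- lab[, , i]
    if (max(sl) > 1L) {
      counts <- tabulate(sl[sl > 0L])
      keep <- which.max(counts)
      filled[, , i] <- sl == keep
    }
  }
  aperm(filled, c(3, 1, 2)) > 0
}

#' Classify voxels into tissue classes by HU thresholds within masks
#'
#' Applies the CT body-composition classification rule: fat voxels have HU
#' in \[-190, -30\] and muscle voxels HU in \[-29, +150\] (both bands
#' inclusive; with integer HU the bands are adjacent and disjoint). Fat
#' inside the abdominal-cavity mask is visceral fat; fat inside the body
#' but outside the cavity is subcutaneous fat. Muscle-range HU counts as
#' skeletal muscle only inside the muscle-compartment mask; fat-range HU
#' inside the muscle compartment is still fat (intramuscular fat is not
#' muscle). Everything else inside the body is "other"; everything outside
#' the body mask is background regardless of HU.
#'
#' @param vol A `labeled_volume` (or any list with integer `hu`, `spacing`,
#'   `landmarks`).
#' @param masks A [mask_set()] congruent with the volume.
#' @return An object of class `tissue_map`: integer `class` array (codes
#'   from [tissue_classes()], `background = 0`), `spacing`, `landmarks`,
#'   and `lean` (logical array: in-body voxels with HU >= -29, the
#'   lean-tissue definition used for lean body mass).
#' @export
classify_voxels <- function(vol, masks) {
  stopifnot(inherits(masks, "mask_set"))
  hu <- vol$hu
  if (!identical(dim(hu), dim(masks$body)))
    stop("mask shape ", paste(dim(masks$body), collapse = "x"),
         " does not match volume shape ", paste(dim(hu), collapse = "x"))
  bands <- ct_constants$hu_bands
  fat <- hu >= bands$fat[1] & hu <= bands$fat[2] & masks$body
  mus <- hu >= bands$muscle[1] & hu <= bands$muscle[2] &
    masks$muscle_compartment & !fat
  cls <- array(.map_classes["background"], dim = dim(hu))
  cls[masks$body] <- .map_classes["other"]
  cls[mus] <- .map_classes["muscle"]
  cls[fat & masks$cavity] <- .map_classes["visceral_fat"]
  cls[fat & !masks$cavity] <- .map_classes["subcutaneous_fat"]
  structure(list(class = cls, spacing = vol$spacing,
                 landmarks = vol$landmarks,
                 lean = masks$body & hu >= bands$muscle[1]),
            class = "tissue_map")
}

#' Count voxels of a tissue class
#'
#' @param map A `tissue_map` from [classify_voxels()].
#' @param cls Class name: one of `"muscle"`, `"visceral_fat"`,
#'   `"subcutaneous_fat"`, `"other"`, `"background"`, `"fat"` (visceral +
#'   subcutaneous) or `"lean"` (in-body HU >= -29).
#' @param within Optional 1-based inclusive slice range `c(from, to)`;
#'   an empty range (`from > to`) yields 0.
#' @return Exact integer voxel count.
#' @export
count_voxels <- function(map, cls, within = NULL) {
  stopifnot(inherits(map, "tissue_map"))
  sel_array <- switch(cls,
    fat = map$class == .map_classes["visceral_fat"] |
          map$class == .map_classes["subcutaneous_fat"],
    lean = map$lean,
    {
      if (!cls %in% names(.map_classes)) stop("unknown tissue class: ", cls)
      map$class == .map_classes[[cls]]
    })
  if (is.null(within)) return(sum(sel_array))
  from <- as.integer(within[1]); to <- as.integer(within[2])
  if (from > to) return(0L)
  nz <- dim(map$class)[1]
  if (from < 1L || to > nz) stop("slice range outside the volume")
  sum(sel_array[from:to, , , drop = FALSE])
}

#' Per-slice cross-sectional area of a tissue class
#'
#' @param map A `tissue_map`.
#' @param cls Tissue class (see [count_voxels()]).
#' @param slice 1-based slice index.
#' @return Area in cm^2 (`pixel count * dy * dx / 100`).
#' @export
slice_area_cm2 <- function(map, cls, slice) {
  n <- count_voxels(map, cls, within = c(slice, slice))
  n * map$spacing[2] * map$spacing[3] / 100
}

#' @export
print.tissue_map <- function(x, ...) {
  d <- dim(x$class)
  cat("tissue map:", paste(d, collapse = " x "), "voxels\n")
  counts <- vapply(setdiff(names(.map_classes), "background"),
                   function(cl) count_voxels(x, cl), integer(1))
  print(counts)
  invisible(x)
}
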
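#' Specification of a synthetic labeled CT phantom
#'
#' Defines the geometry, tissue properties and acquisition landmarks of a
#' torso-like CT phantom built from nested elliptic cylinders: from the
#' outside in, air, a subcutaneous fat shell, a skeletal-muscle ring, and a
#' core containing an abdominal cavity (visceral fat mixed with organ
#' tissue), organ tissue, and a central bone column. Every voxel carries a
#' ground-truth tissue label, so downstream measurements can be compared
#' with analytically known masses.
#'
#' Slices run cranial to caudal (slice 1 is the most cranial); landmark
#' indices are 1-based and ordered `eyes < l3 < ischia`. The acquisition
#' window of a clinical scan (ischia to eyes) corresponds to slices
#' `eyes:ischia` inclusive. `profile` scales the body cross-section per
#' slice (head slices narrower than the torso); cavity and bone are clamped
#' inside the muscle ring wherever the profile pinches the body.
#'
#' @param n_slices Number of axial slices.
#' @param grid Integer length-2, in-plane matrix size `(ny, nx)`.
#' @param spacing Numeric length-3 voxel spacing `(dz, dy, dx)` in mm.
#' @param body_semiaxes Length-2, torso body ellipse semi-axes `(x, y)` mm.
#' @param fat_shell_mm Subcutaneous fat shell thickness, mm.
#' @param muscle_ring_mm Muscle ring thickness, mm.
#' @param cavity_semiaxes Length-2 cavity ellipse semi-axes `(x, y)` mm at
#'   profile 1; clamped per slice to stay inside the muscle ring.
#' @param visceral_fraction Fraction of (non-bone) cavity voxels labeled
#'   visceral fat; the remainder is organ ("other") tissue.
#' @param bone_radius_mm Radius of the central bone column, mm.
#' @param landmarks Named integer vector with 1-based slice indices `eyes`,
#'   `l3`, `ischia` (must satisfy `1 <= eyes < l3 < ischia <= n_slices`).
#' @param profile Per-slice body scale: either a numeric vector of length
#'   `n_slices`, or `NULL` for the default piecewise profile (0.55 above the
#'   eyes, 1 through the trunk, 0.8 below the ischia).
#' @param hu_means Named numeric, mean HU per tissue class
#'   (`air`, `fat`, `muscle`, `other`, `bone`).
#' @param hu_sd Gaussian HU noise standard deviation (rounded to integer HU).
#' @param height_m Patient height in metres.
#' @param sex `"male"` or `"female"`.
#' @param seed Integer RNG seed; compartment noise uses sub-streams derived
#'   deterministically from it.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(n_slices = 256L,
                         grid = c(128L, 128L),
                         spacing = c(2, 3, 3),
                         body_semiaxes = c(170, 110),
                         fat_shell_mm = 15,
                         muscle_ring_mm = 12,
                         cavity_semiaxes = c(135, 80),
                         visceral_fraction = 0.35,
                         bone_radius_mm = 15,
                         landmarks = c(eyes = 26L, l3 = 140L, ischia = 204L),
                         profile = NULL,
                         hu_means = c(air = -1000, fat = -100, muscle = 40,
                                      other = 55, bone = 700),
                         hu_sd = 10,
                         height_m = 1.75,
                         sex = "male",
                         seed = 1L) {
  spec <- list(n_slices = as.integer(n_slices), grid = as.integer(grid),
               spacing = as.numeric(spacing),
               body_semiaxes = as.numeric(body_semiaxes),
               fat_shell_mm = as.numeric(fat_shell_mm),
               muscle_ring_mm = as.numeric(muscle_ring_mm),
               cavity_semiaxes = as.numeric(cavity_semiaxes),
               visceral_fraction = as.numeric(visceral_fraction),
               bone_radius_mm = as.numeric(bone_radius_mm),
               landmarks = c(eyes = as.integer(landmarks[["eyes"]]),
                             l3 = as.integer(landmarks[["l3"]]),
                             ischia = as.integer(landmarks[["ischia"]])),
               profile = profile,
               hu_means = hu_means, hu_sd = as.numeric(hu_sd),
               height_m = as.numeric(height_m), sex = sex,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(spec$n_slices >= 1L, length(spec$grid) == 2L, all(spec$grid >= 4L))
  if (any(spec$spacing <= 0)) stop("voxel spacing must be positive")
  if (spec$fat_shell_mm < 0 || spec$muscle_ring_mm < 0 ||
      spec$bone_radius_mm < 0)
    stop("shell/ring thicknesses and bone radius must be >= 0")
  if (spec$visceral_fraction < 0 || spec$visceral_fraction > 1)
    stop("visceral_fraction must be in [0, 1]")
  lm <- spec$landmarks
  if (!(1L <= lm["eyes"] && lm["eyes"] < lm["l3"] &&
        lm["l3"] < lm["ischia"] && lm["ischia"] <= spec$n_slices))
    stop("landmarks must satisfy 1 <= eyes < l3 < ischia <= n_slices")
  prof <- phantom_profile(spec)
  inner <- pmin(spec$body_semiaxes[1], spec$body_semiaxes[2]) * min(prof) -
    spec$fat_shell_mm - spec$muscle_ring_mm
  if (inner <= 0)
    stop("fat shell plus muscle ring exceed the body semi-axes ",
         "(negative inner-core thickness)")
  if (!spec$sex %in% c("male", "female"))
    stop("sex must be 'male' or 'female'")
  if (spec$height_m <= 0) stop("height must be positive")
  invisible(spec)
}

phantom_profile <- function(spec) {
  if (!is.null(spec$profile)) {
    stopifnot(length(spec$profile) == spec$n_slices, all(spec$profile > 0))
    return(as.numeric(spec$profile))
  }
  prof <- rep(1, spec$n_slices)
  lm <- spec$landmarks
  if (lm["eyes"] > 1L) prof[seq_len(lm["eyes"] - 1L)] <- 0.55
  if (lm["ischia"] < spec$n_slices)
    prof[(lm["ischia"] + 1L):spec$n_slices] <- 0.80
  prof
}

# Deterministic per-compartment RNG sub-streams derived from one seed.
compartment_seeds <- function(seed, n = 8L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a labeled synthetic CT phantom
#'
#' Builds the voxel grid described by a [phantom_spec()]: per-voxel
#' ground-truth tissue labels, integer HU values (class mean plus rounded
#' Gaussian noise), geometric body/cavity/muscle-compartment masks, and
#' exact ground-truth masses (`mass = N * V_voxel * density`, with muscle at
#' 1.06 g/ml and fat at 0.923 g/ml). Generation is fully reproducible for a
#' fixed spec and seed.
#'
#' The generated HU distribution is validated: at least 99% of fat and
#' muscle voxels must fall inside their classification bands, otherwise the
#' noise SD is inconsistent with the class means and an error is raised.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `labeled_volume`: a list with `hu` (integer
#'   array, slice x y x x), `labels` (integer ground-truth codes, see
#'   [tissue_classes()]), `spacing` (dz, dy, dx mm), `landmarks`, `masks`
#'   (a [mask_set()]), `truth_masses` (named, grams), `height_m`, `sex`.
#' @examples
#' vol <- generate_phantom(phantom_spec(n_slices = 24, grid = c(32, 32),
#'   spacing = c(4, 8, 8), landmarks = c(eyes = 4, l3 = 12, ischia = 20)))
#' vol$truth_masses / 1000  # kg
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  ny <- spec$grid[1]; nx <- spec$grid[2]; nz <- spec$n_slices
  dz <- spec$spacing[1]; dy <- spec$spacing[2]; dx <- spec$spacing[3]
  prof <- phantom_profile(spec)
  seeds <- compartment_seeds(spec$seed)

  # voxel-centre coordinates (mm), origin at the grid centre
  yc <- (seq_len(ny) - (ny + 1) / 2) * dy
  xc <- (seq_len(nx) - (nx + 1) / 2) * dx
  Y2 <- matrix(yc^2, ny, nx)
  X2 <- matrix(xc^2, ny, nx, byrow = TRUE)
  R2 <- Y2 + X2  # squared distance to axis, for the bone column

  in_ellipse <- function(ax, ay) {
    if (ax <= 0 || ay <= 0) return(matrix(FALSE, ny, nx))
    X2 / ax^2 + Y2 / ay^2 <= 1
  }

  labels <- array(.classes["air"], dim = c(nz, ny, nx))
  cavity_mask <- array(FALSE, dim = c(nz, ny, nx))
  muscle_mask <- array(FALSE, dim = c(nz, ny, nx))

  set.seed(seeds[1])  # visceral/organ voxel mixture stream
  for (i in seq_len(nz)) {
    ax <- spec$body_semiaxes[1] * prof[i]
    ay <- spec$body_semiaxes[2] * prof[i]
    body <- in_ellipse(ax, ay)
    fat_in <- in_ellipse(ax - spec$fat_shell_mm, ay - spec$fat_shell_mm)
    core <- in_ellipse(ax - spec$fat_shell_mm - spec$muscle_ring_mm,
                       ay - spec$fat_shell_mm - spec$muscle_ring_mm)
    cav <- in_ellipse(min(spec$cavity_semiaxes[1] * prof[i],
                          ax - spec$fat_shell_mm - spec$muscle_ring_mm - dy),
                      min(spec$cavity_semiaxes[2] * prof[i],
                          ay - spec$fat_shell_mm - spec$muscle_ring_mm - dy))
    bone <- R2 <= min(spec$bone_radius_mm * prof[i],
                      0.9 * spec$cavity_semiaxes[2] * prof[i])^2 & core
    sl <- matrix(.classes["air"], ny, nx)
    sl[body & !fat_in] <- .classes["subcutaneous_fat"]
    sl[fat_in & !core] <- .classes["muscle"]
    sl[core] <- .classes["other"]
    cav_free <- cav & !bone
    n_cav <- sum(cav_free)
    if (n_cav > 0 && spec$visceral_fraction > 0) {
      pick <- runif(n_cav) < spec$visceral_fraction
      idx <- which(cav_free)[pick]
      sl[idx] <- .classes["visceral_fat"]
    }
    sl[bone] <- .classes["bone"]
    labels[i, , ] <- sl
    cavity_mask[i, , ] <- cav_free
    muscle_mask[i, , ] <- fat_in & !core
  }

  hu <- array(NA_integer_, dim = dim(labels))
  hu_class <- c(air = "air", subcutaneous_fat = "fat", muscle = "muscle",
                visceral_fat = "fat", other = "other", bone = "bone")
  for (k in seq_along(.classes)) {
    cls <- names(.classes)[k]
    idx <- which(labels == .classes[[cls]])
    if (!length(idx)) next
    set.seed(seeds[1L + k])
    hu[idx] <- as.integer(round(rnorm(length(idx),
                                      mean = spec$hu_means[[hu_class[cls]]],
                                      sd = spec$hu_sd)))
  }

  vol <- structure(list(
    hu = hu, labels = labels, spacing = spec$spacing,
    landmarks = spec$landmarks,
    masks = mask_set(body = labels != .classes["air"],
                     cavity = cavity_mask, muscle_compartment = muscle_mask),
    truth_masses = truth_masses_from_labels(labels, spec$spacing),
    height_m = spec$height_m, sex = spec$sex
  ), class = "labeled_volume")

  check_band_purity(vol)
  vol
}

check_band_purity <- function(vol, min_frac = 0.99) {
  bands <- ct_constants$hu_bands
  fat_idx <- vol$labels == .classes["subcutaneous_fat"] |
    vol$labels == .classes["visceral_fat"]
  mus_idx <- vol$labels == .classes["muscle"]
  ok <- TRUE
  if (any(fat_idx)) {
    h <- vol$hu[fat_idx]
    ok <- ok && mean(h >= bands$fat[1] & h <= bands$fat[2]) >= min_frac
  }
  if (any(mus_idx)) {
    h <- vol$hu[mus_idx]
    ok <- ok && mean(h >= bands$muscle[1] & h <= bands$muscle[2]) >= min_frac
  }
  if (!ok)
    stop("HU noise SD too large: tissue HU leaves its classification band ",
         "in more than 1% of voxels")
  invisible(TRUE)
}

#' Ground-truth tissue classes of a labeled volume
#'
#' @return Named integer vector mapping class names
#'   (`air`, `subcutaneous_fat`, `muscle`, `visceral_fat`, `other`, `bone`)
#'   to the integer codes used in `labels` arrays.
#' @export
tissue_classes <- function() .classes

#' Voxel volume in millilitres
#'
#' @param x A `labeled_volume`, `tissue_map`, or numeric length-3 spacing
#'   `(dz, dy, dx)` in mm.
#' @return Voxel volume in ml (`dz * dy * dx / 1000`).
#' @export
voxel_volume_ml <- function(x) {
  sp <- if (is.numeric(x)) x else x$spacing
  stopifnot(length(sp) == 3, all(sp > 0))
  prod(sp) / 1000
}

truth_masses_from_labels <- function(labels, spacing) {
  vv <- voxel_volume_ml(spacing)
  dens <- c(subcutaneous_fat = ct_constants$density[["fat"]],
            muscle = ct_constants$density[["muscle"]],
            visceral_fat = ct_constants$density[["fat"]],
            other = ct_constants$density[["other"]],
            bone = ct_constants$density[["bone"]])
  vapply(names(dens), function(cls) {
    sum(labels == .classes[[cls]]) * vv * dens[[cls]]
  }, numeric(1))
}

#' Truncate a labeled volume to a slice range (simulate a limited FOV)
#'
#' Clinical PET/CT is acquired roughly from mid-thigh to the base of the
#' skull; body parts below the ischia and above the eyes are missing and
#' must be extrapolated. This helper crops a phantom to a slice range so
#' that extrapolation-factor recovery can be exercised against ground truth.
#'
#' @param vol A `labeled_volume`.
#' @param keep_from,keep_to 1-based inclusive slice range to retain.
#' @return A `labeled_volume` covering only the retained slices: landmarks
#'   are re-indexed (landmarks falling outside the range become `NA`),
#'   masks are cropped, and `truth_masses` are recomputed for the retained
#'   part so that retained + removed masses equal the whole-body masses.
#' @export
truncate_fov <- function(vol, keep_from, keep_to) {
  stopifnot(inherits(vol, "labeled_volume"))
  nz <- dim(vol$hu)[1]
  keep_from <- as.integer(keep_from); keep_to <- as.integer(keep_to)
  if (keep_from < 1L || keep_to > nz || keep_from > keep_to)
    stop("slice range [", keep_from, ", ", keep_to, "] is empty or outside ",
         "the volume (", nz, " slices)")
  sel <- keep_from:keep_to
  lm <- vol$landmarks - keep_from + 1L
  lm[vol$landmarks < keep_from | vol$landmarks > keep_to] <- NA_integer_
  out <- structure(list(
    hu = vol$hu[sel, , , drop = FALSE],
    labels = vol$labels[sel, , , drop = FALSE],
    spacing = vol$spacing, landmarks = lm,
    masks = mask_set(body = vol$masks$body[sel, , , drop = FALSE],
                     cavity = vol$masks$cavity[sel, , , drop = FALSE],
                     muscle_compartment =
                       vol$masks$muscle_compartment[sel, , , drop = FALSE]),
    truth_masses = truth_masses_from_labels(
      vol$labels[sel, , , drop = FALSE], vol$spacing),
    height_m = vol$height_m, sex = vol$sex
  ), class = "labeled_volume")
  out
}

#' Restrict a volume to its acquisition window (eyes to ischia)
#'
#' @param vol A `labeled_volume` with `eyes` and `ischia` landmarks.
#' @return `truncate_fov(vol, eyes, ischia)`.
#' @export
acquisition_window <- function(vol) {
  lm <- vol$landmarks
  if (is.null(lm) || anyNA(lm[c("eyes", "ischia")]))
    stop("volume lacks eyes/ischia landmarks")
  truncate_fov(vol, lm[["eyes"]], lm[["ischia"]])
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat("labeled CT volume:", paste(d, collapse = " x "),
      "voxels, spacing", paste(x$spacing, collapse = "x"), "mm\n")
  cat("landmarks (slice):",
      paste(names(x$landmarks), x$landmarks, collapse = ", "), "\n")
  cat("truth masses (kg):\n")
  print(round(x$truth_masses / 1000, 3))
  invisible(x)
}
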
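# Small phantom and cohort fixtures shared across tests; everything is
# generated in code at test time.

# Tiny flat-profile phantom: no per-slice clamping, so geometry is the plain
# nested-ellipse rule and brute-force oracles apply exactly.
tiny_spec <- function(seed = 1L, hu_sd = 10, n_slices = 20L,
                      landmarks = c(eyes = 3L, l3 = 10L, ischia = 17L),
                      visceral_fraction = 0.35, fat_shell_mm = 9,
                      body_semiaxes = c(60, 60), cavity_semiaxes = c(30, 24)) {
  phantom_spec(n_slices = n_slices, grid = c(24L, 24L), spacing = c(4, 6, 6),
               body_semiaxes = body_semiaxes, fat_shell_mm = fat_shell_mm,
               muscle_ring_mm = 9, cavity_semiaxes = cavity_semiaxes,
               visceral_fraction = visceral_fraction, bone_radius_mm = 6,
               landmarks = landmarks, profile = rep(1, n_slices),
               hu_sd = hu_sd, seed = seed)
}

# Medium phantom for geometry-accuracy checks (finer in-plane grid).
medium_spec <- function(seed = 1L, ...) {
  phantom_spec(n_slices = 40L, grid = c(96L, 96L), spacing = c(4, 2.5, 2.5),
               body_semiaxes = c(100, 100), fat_shell_mm = 12,
               muscle_ring_mm = 12, cavity_semiaxes = c(60, 50),
               bone_radius_mm = 10,
               landmarks = c(eyes = 5L, l3 = 20L, ischia = 35L),
               profile = rep(1, 40), seed = seed, ...)
}

# Independent per-voxel membership oracle for the flat-profile phantom
# geometry: a plain nested loop, no vectorization shared with the package.
brute_force_labels <- function(spec) {
  stopifnot(all(phantom_profile_oracle(spec) == 1))
  ny <- spec$grid[1]; nx <- spec$grid[2]
  dy <- spec$spacing[2]; dx <- spec$spacing[3]
  ax <- spec$body_semiaxes[1]; ay <- spec$body_semiaxes[2]
  t1 <- spec$fat_shell_mm; t2 <- spec$muscle_ring_mm
  cx <- min(spec$cavity_semiaxes[1], ax - t1 - t2 - dy)
  cy <- min(spec$cavity_semiaxes[2], ay - t1 - t2 - dy)
  rb <- min(spec$bone_radius_mm, 0.9 * spec$cavity_semiaxes[2])
  out <- array("air", dim = c(spec$n_slices, ny, nx))
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      y <- (j - (ny + 1) / 2) * dy
      x <- (i - (nx + 1) / 2) * dx
      lab <- "air"
      if ((x / ax)^2 + (y / ay)^2 <= 1) {
        lab <- "subcutaneous_fat"
        if ((x / (ax - t1))^2 + (y / (ay - t1))^2 <= 1) {
          lab <- "muscle"
          if ((x / (ax - t1 - t2))^2 + (y / (ay - t1 - t2))^2 <= 1) {
            lab <- "other"  # core; cavity mixture is stochastic
            if (x^2 + y^2 <= rb^2) lab <- "bone"
            else if ((x / cx)^2 + (y / cy)^2 <= 1) lab <- "cavity"
          }
        }
      }
      out[, j, i] <- lab
    }
  }
  out
}

phantom_profile_oracle <- function(spec) {
  if (!is.null(spec$profile)) spec$profile else stop("flat profile expected")
}

# Standard planted-effect survival cohort used in recovery tests.
planted_cohort <- function(seed, n = 500, hr = 2, admin = 36,
                           n_noise = 0) {
  markers <- list(planted = list(dist = "binary", p = 0.5))
  if (n_noise > 0)
    markers <- c(markers, setNames(
      lapply(seq_len(n_noise),
             function(i) list(dist = "normal", mean = 0, sd = 1)),
      paste0("noise", seq_len(n_noise))))
  simulate_cohort(cohort_spec(n = n, markers = markers,
                              betas = c(planted = log(hr)),
                              admin_censor_time = admin, seed = seed))
}
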
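test_that("mass formula reproduces the density constants", {
  expect_equal(compute_mass(1000, 0.004, 1.06), 4.24)
  expect_equal(compute_mass(0, 0.004, 1.06), 0)
  expect_equal(compute_mass(1000, 0.004, 0.923), 3.692)
  expect_error(compute_mass(-1, 0.004, 1.06), "non-negative")
  # linear in count and in voxel volume
  expect_equal(compute_mass(500, 0.004, 1.06) * 2,
               compute_mass(1000, 0.004, 1.06))
  expect_equal(compute_mass(1000, 0.002, 1.06) * 2,
               compute_mass(1000, 0.004, 1.06))
})

test_that("k calibration: no out-of-window tissue gives k = 1, slice shares give exact ratios", {
  # all slices inside the eyes:ischia window except none -> k = 1
  spec_all_in <- tiny_spec(hu_sd = 0, n_slices = 20L,
                           landmarks = c(eyes = 1L, l3 = 10L, ischia = 20L))
  k1 <- calibrate_k(generate_phantom(spec_all_in))
  expect_equal(k1$k_muscle, 1)
  expect_equal(k1$k_fat, 1)

  # flat profile, 2 of 20 slices below the ischia: exactly 10% of muscle
  # voxels outside the window -> k = 1/0.9 (noise-free labels are exact;
  # visceral fraction 0 so fat is the deterministic shell only)
  spec_10 <- tiny_spec(hu_sd = 0, n_slices = 20L, visceral_fraction = 0,
                       landmarks = c(eyes = 1L, l3 = 9L, ischia = 18L))
  k <- calibrate_k(generate_phantom(spec_10))
  expect_equal(k$k_muscle, 1 / 0.9, tolerance = 1e-12)
  expect_equal(k$k_fat, 1 / 0.9, tolerance = 1e-12)
})

test_that("k is the arithmetic mean of per-volume ratios", {
  # 1 and 3 of 20 slices outside the window -> ratios 20/19 and 20/17
  v1 <- generate_phantom(tiny_spec(hu_sd = 0, visceral_fraction = 0,
    landmarks = c(eyes = 1L, l3 = 10L, ischia = 19L)))
  v2 <- generate_phantom(tiny_spec(hu_sd = 0, visceral_fraction = 0,
    landmarks = c(eyes = 2L, l3 = 10L, ischia = 18L)))
  k <- calibrate_k(list(v1, v2))
  expect_equal(k$k_muscle, mean(c(20 / 19, 20 / 17)), tolerance = 1e-12)
  expect_identical(k$n_volumes, 2L)
})

test_that("calibration input is validated", {
  vol <- generate_phantom(tiny_spec())
  nolm <- vol; nolm$landmarks <- c(eyes = NA_integer_, l3 = 2L, ischia = 3L)
  expect_error(calibrate_k(list(nolm)), "landmarks")
  expect_error(extrapolation_factors(0.5, 1.2), ">= 1")
  expect_error(extrapolation_factors(Inf, 1.2), "finite")
})

test_that("body composition: conservation, normalization, mask requirement", {
  vol <- generate_phantom(tiny_spec(seed = 8))
  map <- classify_voxels(vol, vol$masks)
  k <- extrapolation_factors(1.17, 1.23)
  bc <- compute_body_composition(map, vol$masks, k, height = 1.75)
  m <- bc$masses_kg
  expect_identical(m[["FBM"]], m[["VFM"]] + m[["SCFM"]])  # exact
  expect_equal(bc$indices_kgm2[["FBM"]], m[["FBM"]] / 1.75^2,
               tolerance = 1e-12)
  # MBM = 30 kg at 1.75 m -> 9.796 kg/m^2
  expect_equal(round(30 / 1.75^2, 3), 9.796)
  expect_error(compute_body_composition(map, NULL, k, 1.75), "mask")
  # indices strictly decrease as height increases
  taller <- compute_body_composition(map, vol$masks, k, height = 1.85)
  expect_true(all(taller$indices_kgm2 < bc$indices_kgm2))
  expect_identical(taller$masses_kg, bc$masses_kg)
})

test_that("with k = 1 an untruncated phantom recovers truth masses within 1%", {
  vol <- generate_phantom(tiny_spec(seed = 14))
  map <- classify_voxels(vol, vol$masks)
  bc <- compute_body_composition(map, vol$masks, extrapolation_factors(1, 1),
                                 vol$height_m)
  truth_kg <- vol$truth_masses / 1000
  expect_lt(abs(bc$masses_kg[["MBM"]] / truth_kg[["muscle"]] - 1), 0.01)
  expect_lt(abs(bc$masses_kg[["VFM"]] / truth_kg[["visceral_fat"]] - 1), 0.01)
  expect_lt(abs(bc$masses_kg[["FBM"]] /
                  (truth_kg[["visceral_fat"]] +
                     truth_kg[["subcutaneous_fat"]]) - 1), 0.01)
})

test_that("extrapolated estimates are invariant to the truncation point when calibration matches", {
  # two truncation levels, each with a matched calibration phantom family
  spec <- tiny_spec(hu_sd = 0, n_slices = 20L,
                    landmarks = c(eyes = 3L, l3 = 10L, ischia = 17L))
  vol <- generate_phantom(spec)
  truth_mbm <- vol$truth_masses[["muscle"]] / 1000
  for (lm in list(c(eyes = 3L, l3 = 10L, ischia = 17L),
                  c(eyes = 5L, l3 = 10L, ischia = 15L))) {
    sp <- tiny_spec(hu_sd = 0, n_slices = 20L, landmarks = lm)
    k <- calibrate_k(lapply(1:2, function(s) {
      sp2 <- sp; sp2$seed <- 100L + s; generate_phantom(sp2)
    }))
    v <- generate_phantom(sp)
    fov <- acquisition_window(v)
    bc <- compute_body_composition(classify_voxels(fov, fov$masks),
                                   fov$masks, k, v$height_m)
    expect_equal(bc$masses_kg[["MBM"]], truth_mbm, tolerance = 1e-6)
  }
})
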
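test_that("phantom geometry matches an independent per-voxel membership oracle", {
  spec <- tiny_spec(seed = 3)
  vol <- generate_phantom(spec)
  oracle <- brute_force_labels(spec)
  cls <- tissue_classes()

  # deterministic compartments match the voxel-loop oracle exactly
  expect_identical(sum(vol$labels == cls["muscle"]), sum(oracle == "muscle"))
  expect_identical(sum(vol$labels == cls["subcutaneous_fat"]),
                   sum(oracle == "subcutaneous_fat"))
  expect_identical(sum(vol$labels == cls["bone"]), sum(oracle == "bone"))
  expect_identical(sum(vol$labels == cls["air"]), sum(oracle == "air"))
  # the cavity mixture splits the oracle's cavity region
  expect_identical(sum(vol$labels == cls["visceral_fat"]) +
                     sum(vol$labels == cls["other"]),
                   sum(oracle == "cavity") + sum(oracle == "other"))
  # visceral fat lies only in the oracle's cavity region
  expect_true(all(oracle[vol$labels == cls["visceral_fat"]] == "cavity"))
})

test_that("truth masses follow mass = N * V_voxel * density exactly", {
  vol <- generate_phantom(tiny_spec(seed = 5))
  vv <- voxel_volume_ml(vol)
  cls <- tissue_classes()
  expect_identical(vol$truth_masses[["muscle"]],
                   sum(vol$labels == cls["muscle"]) * vv * 1.06)
  expect_identical(vol$truth_masses[["visceral_fat"]],
                   sum(vol$labels == cls["visceral_fat"]) * vv * 0.923)
  expect_identical(vv, prod(c(4, 6, 6)) / 1000)
})

test_that("empty compartments yield zero truth mass", {
  vol <- generate_phantom(tiny_spec(fat_shell_mm = 0, visceral_fraction = 0))
  expect_identical(vol$truth_masses[["subcutaneous_fat"]], 0)
  expect_identical(vol$truth_masses[["visceral_fat"]], 0)
})

test_that("generation is bit-identical for a fixed spec and seed", {
  a <- generate_phantom(tiny_spec(seed = 11))
  b <- generate_phantom(tiny_spec(seed = 11))
  expect_identical(a$hu, b$hu)
  expect_identical(a$labels, b$labels)
  c <- generate_phantom(tiny_spec(seed = 12))
  expect_false(identical(a$hu, c$hu))
})

test_that("invalid geometry and excessive noise are rejected", {
  expect_error(tiny_spec(fat_shell_mm = -1), "thickness")
  expect_error(phantom_spec(body_semiaxes = c(20, 20), fat_shell_mm = 15,
                            muscle_ring_mm = 12),
               "negative inner-core")
  expect_error(phantom_spec(landmarks = c(eyes = 50, l3 = 40, ischia = 204)),
               "landmarks")
  # muscle mean 40 with SD 150 floods both band edges
  expect_error(generate_phantom(tiny_spec(hu_sd = 150)), "noise")
})

test_that("truncation re-indexes landmarks and conserves per-class counts", {
  vol <- generate_phantom(tiny_spec(seed = 7))
  cls <- tissue_classes()

  # identity truncation
  full <- truncate_fov(vol, 1, 20)
  expect_identical(full$truth_masses, vol$truth_masses)
  expect_identical(full$landmarks, vol$landmarks)

  inside <- truncate_fov(vol, 5, 14)
  outside_a <- truncate_fov(vol, 1, 4)
  outside_b <- truncate_fov(vol, 15, 20)
  cls <- tissue_classes()
  for (cl in setdiff(names(cls), "air")) {
    # voxel counts are conserved exactly
    expect_identical(sum(inside$labels == cls[[cl]]) +
                       sum(outside_a$labels == cls[[cl]]) +
                       sum(outside_b$labels == cls[[cl]]),
                     sum(vol$labels == cls[[cl]]))
    # masses agree up to float summation order
    expect_equal(inside$truth_masses[[cl]] + outside_a$truth_masses[[cl]] +
                   outside_b$truth_masses[[cl]],
                 vol$truth_masses[[cl]], tolerance = 1e-12)
  }
  expect_identical(inside$landmarks[["l3"]], 6L)
  expect_true(is.na(inside$landmarks[["eyes"]]))

  expect_error(truncate_fov(vol, 10, 5), "empty")
  expect_error(truncate_fov(vol, 0, 5), "empty|outside")
})

test_that("flat-profile phantom truncated at the ischia retains the exact slice share of muscle", {
  # ischia at slice 18 of 20: sub-ischial slices hold exactly 2/20 = 10%
  # of muscle voxels (flat profile -> identical per-slice geometry)
  spec <- tiny_spec(landmarks = c(eyes = 1L, l3 = 9L, ischia = 18L))
  vol <- generate_phantom(spec)
  cls <- tissue_classes()
  kept <- truncate_fov(vol, 1, 18)
  expect_identical(sum(kept$labels == cls["muscle"]) * 10L,
                   sum(vol$labels == cls["muscle"]) * 9L)
})

test_that("acquisition_window crops to the eyes:ischia slice range", {
  vol <- generate_phantom(tiny_spec())
  fov <- acquisition_window(vol)
  expect_identical(dim(fov$hu)[1], 15L)  # slices 3..17
  expect_identical(fov$landmarks[["eyes"]], 1L)
  expect_identical(fov$landmarks[["ischia"]], 15L)
  fov2 <- truncate_fov(vol, 4, 20)
  expect_error(acquisition_window(fov2), "landmark")
})
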
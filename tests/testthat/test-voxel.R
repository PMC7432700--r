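# Voxelization and connected-component vesicle detection.

test_that("voxel spacing validation and empty scenes behave", {
  params <- quick_params(total_sv = 0L)
  params$n_dense_core <- 0L
  scene <- generate_scene(params)
  expect_error(voxelize_scene(scene, spacing = c(5, 5)), "3 positive")
  expect_error(voxelize_scene(scene, spacing = c(1e7, 5, 50)), "exceeds")
  vol <- voxelize_scene(scene, spacing = c(20, 20, 50))
  expect_identical(nrow(vol$voxels$vesicle), 0L)
  det <- detect_vesicles_voxel(vol)
  expect_identical(nrow(det), 0L)
})

test_that("default anisotropic spacing has a 50 nm z pitch", {
  vol <- voxelize_scene(generate_scene(quick_params(total_sv = 5L)))
  expect_identical(vol$spacing, c(5, 5, 50))
})

test_that("foreground voxel volume approximates the sphere volume", {
  params <- quick_params(total_sv = 0L)
  params$n_dense_core <- 0L
  scene <- generate_scene(params)
  scene$vesicles <- tibble::tibble(track_id = 1L, x = 0, y = 0, z = 0,
                                   radius = 250, pool = "resting_gt200",
                                   docked = FALSE, dense_core = FALSE,
                                   p_true = 300, az = 1L)
  vol <- voxelize_scene(scene, spacing = c(5, 5, 5))
  v_est <- nrow(vol$voxels$vesicle) * 125
  expect_equal(v_est, 4 / 3 * pi * 250^3, tolerance = 0.02)
})

test_that("well-separated spheres yield one detection each at the truth", {
  params <- quick_params(total_sv = 0L)
  params$n_dense_core <- 0L
  scene <- generate_scene(params)
  scene$vesicles <- tibble::tibble(track_id = 1:2, x = c(0, 200), y = c(0, 0),
                                   z = c(0, 150), radius = 17,
                                   pool = "resting_gt200", docked = FALSE,
                                   dense_core = FALSE, p_true = 300, az = 1L)
  vol <- voxelize_scene(scene, spacing = c(5, 5, 5))
  det <- detect_vesicles_voxel(vol)
  expect_identical(nrow(det), 2L)
  det <- det[order(det$x), ]
  expect_lt(abs(det$x[1L] - 0), 5)
  expect_lt(abs(det$z[2L] - 150), 5)
})

test_that("anisotropic detection counts are at most the isotropic ones", {
  # the partial-volume bias of coarse z sampling: merged or missed vesicles
  params <- quick_params(rng_seed = 17L, total_sv = 250L)
  scene <- generate_scene(params)
  n_iso <- nrow(detect_vesicles_voxel(voxelize_scene(scene, c(5, 5, 5))))
  n_aniso <- nrow(detect_vesicles_voxel(voxelize_scene(scene, c(5, 5, 50))))
  expect_lte(n_aniso, n_iso)
  expect_lte(n_iso, nrow(scene$vesicles))
})

test_that("dense voxel arrays reconstruct from the sparse store", {
  params <- quick_params(total_sv = 10L)
  scene <- generate_scene(params)
  vol <- voxelize_scene(scene, spacing = c(10, 10, 50))
  a <- voxel_array(vol, "vesicle")
  expect_identical(dim(a), vol$dims)
  expect_identical(sum(a), nrow(vol$voxels$vesicle))
})
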
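# Ground-truth scene generator.

test_that("pool-bin rounding reproduces the layer-5 preset counts exactly", {
  sp <- scene_preset("L5_TLN")
  counts <- pool_counts_from_spec(sp$pools, sp$total_sv)
  expect_identical(sp$total_sv, 1519L)
  expect_identical(unname(counts),
                   c(5L, 10L, 58L, 182L, 1264L))
  sp4 <- scene_preset("L4_TLN")
  counts4 <- pool_counts_from_spec(sp4$pools, sp4$total_sv)
  expect_identical(sp4$total_sv, 1821L)
  expect_identical(sum(counts4), 1821L)
  expect_identical(unname(counts4[c("RRP_p10", "RP_60_200", "resting_gt200")]),
                   c(20L, 382L, 1252L))
})

test_that("presets carry the published layer means", {
  sp <- scene_preset("L5_TLN")
  expect_equal(sp$bouton_surface_area_target, 6.09e6)
  expect_equal(sp$bouton_volume_target, 0.63e9)
  expect_equal(sp$az_area_targets, 0.23e6)
  expect_equal(sp$cleft$lateral_width, 17.24)
  sp4 <- scene_preset("L4_TLN")
  expect_equal(sp4$az_area_targets, 0.13e6)
  expect_identical(sp4$total_sv, 1821L)
  expect_error(scene_preset("L1_TLN"))
})

test_that("parameter validation rejects inconsistent specifications", {
  expect_error(pool_spec(frac_p10 = 0.5, frac_resting = 0.832), "sum to 1")
  expect_error(pool_spec(docked_fraction = 1.5), "docked_fraction")
  expect_error(cleft_spec(lateral_width = -1), "positive")
  expect_error(scene_params(n_az = 4L), "n_az")
  expect_error(scene_params(bouton_surface_area_target = -1), "positive")
})

test_that("generated scenes hit their targets and satisfy the invariants", {
  params <- quick_params(rng_seed = 7L)
  scene <- generate_scene(params)
  expect_s3_class(scene, "syn_scene")
  # areas/volumes within 2%, integer counts exact
  expect_equal(scene$realized$surface_area, params$bouton_surface_area_target,
               tolerance = 0.02)
  expect_equal(scene$realized$volume, params$bouton_volume_target,
               tolerance = 0.02)
  expect_equal(scene$realized$az_areas, params$az_area_targets,
               tolerance = 0.02)
  expect_identical(unname(scene$realized$pool_counts),
                   unname(pool_counts_from_spec(params$pools, params$total_sv)))
  expect_equal(scene$realized$mito_volume_fraction,
               params$mito_volume_fraction_target, tolerance = 0.02)
  # geometric invariants: containment, non-overlap, bin membership by
  # exhaustive point-to-triangle recomputation
  expect_true(validate_scene(scene))
})

test_that("an empty vesicle complement still yields a valid scene", {
  params <- quick_params(total_sv = 0L)
  params$n_dense_core <- 0L
  scene <- generate_scene(params)
  expect_identical(nrow(scene$vesicles), 0L)
  expect_gt(scene$realized$surface_area, 0)
  expect_true(validate_scene(scene))
})

test_that("scene generation is deterministic for a fixed seed", {
  p1 <- quick_params(rng_seed = 11L)
  s1 <- generate_scene(p1)
  s2 <- generate_scene(p1)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_scene_json(s1, f1); write_scene_json(s2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # a different seed gives different geometry
  s3 <- generate_scene(quick_params(rng_seed = 12L))
  expect_false(identical(s1$vesicles$x, s3$vesicles$x))
  unlink(c(f1, f2))
})

test_that("infeasible packing is reported with the binding constraint", {
  params <- quick_params(total_sv = 4000L)
  params$bouton_volume_target <- 0.05e9
  params$bouton_surface_area_target <- 1.2e6
  expect_error(generate_scene(params), "infeasible|fit")
})

test_that("docked vesicles sit in membrane contact and are counted in p10", {
  scene <- generate_scene(quick_params(rng_seed = 3L))
  v <- scene$vesicles
  docked <- v[v$docked, ]
  expect_gt(nrow(docked), 0L)
  expect_true(all(docked$p_true == 0))
  expect_true(all(docked$pool == "RRP_p10"))
})

test_that("mitochondrial volume fraction tracks its target across the stated range", {
  for (frac in c(0.10, 0.15, 0.20)) {
    params <- quick_params(rng_seed = 21L)
    params$mito_volume_fraction_target <- frac
    scene <- generate_scene(params)
    expect_lt(abs(scene$realized$mito_volume_fraction - frac), 0.02)
  }
})
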
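# Serial sectioning and voxel observation models.

test_that("a small sphere fully inside one slab yields exactly one mark", {
  params <- quick_params(total_sv = 0L)
  params$n_dense_core <- 0L
  scene <- generate_scene(params)
  # inject a single vesicle centred at a section mid-plane
  scene$vesicles <- tibble::tibble(track_id = 1L, x = 0, y = 0, z = 10,
                                   radius = 27, pool = "resting_gt200",
                                   docked = FALSE, dense_core = FALSE,
                                   p_true = 300, az = 1L)
  plan <- section_plan(thickness_nominal = 55, thickness_jitter = 0,
                       z0 = 10 - 27.5)
  stack <- section_scene(scene, plan)
  marks <- stack_marks(stack)
  expect_identical(nrow(marks), 1L)
  expect_equal(marks$measured_diameter, 54)
})

test_that("mark counts equal the interval-overlap oracle for a large sphere", {
  params <- quick_params(total_sv = 0L)
  params$n_dense_core <- 0L
  scene <- generate_scene(params)
  r_v <- 180
  scene$vesicles <- tibble::tibble(track_id = 1L, x = 0, y = 0, z = -40,
                                   radius = r_v, pool = "resting_gt200",
                                   docked = FALSE, dense_core = FALSE,
                                   p_true = 300, az = 1L)
  plan <- section_plan(thickness_nominal = 55, thickness_jitter = 0, z0 = -400)
  stack <- section_scene(scene, plan)
  marks <- stack_marks(stack)
  # oracle: count sections whose half-open z interval overlaps the sphere
  s <- stack$sections
  oracle <- sum((-40 - r_v < s$z_hi) & (-40 + r_v > s$z_lo))
  expect_identical(nrow(marks), as.integer(oracle))
})

test_that("thickness jitter keeps every realised thickness within the band", {
  scene <- generate_scene(quick_params(total_sv = 20L))
  stack <- section_scene(scene, section_plan(thickness_nominal = 55,
                                             thickness_jitter = 5),
                         rng_seed = 5L)
  expect_true(all(stack$sections$thickness >= 50))
  expect_true(all(stack$sections$thickness <= 60))
})

test_that("summed contour area times thickness approaches the true volume", {
  # 10 nm slicing of an analytic sphere: Cavalieri within 1%
  st <- sphere_stack(r = 500, dz = 10)
  expect_equal(cavalieri_volume(st, "bouton"), 4 / 3 * pi * 0.5^3,
               tolerance = 0.01)
})

test_that("vesicle marks lie inside the bouton contour of their section", {
  scene <- generate_scene(quick_params(rng_seed = 9L))
  stack <- section_scene(scene, section_plan())
  s <- stack$sections
  inside_all <- logical(0)
  for (i in seq_len(nrow(s))) {
    mk <- s$marks[[i]]
    if (is.null(mk) || !nrow(mk)) next
    bp <- Filter(function(p) identical(p$label, "bouton"), s$polygons[[i]])
    if (!length(bp)) next
    inside <- rep(FALSE, nrow(mk))
    for (p in bp)
      inside <- inside | synmorph:::points_in_polygon(cbind(mk$x, mk$y), p$xy)
    inside_all <- c(inside_all, inside)
  }
  # neighbour-slab profiles are only annotated inside the cell outline; a
  # centre-slab mark can sit marginally outside its mid-plane contour when
  # the membrane is steep between mid-planes, which is rare
  expect_gt(mean(inside_all), 0.99)
})

test_that("ground-truth vesicle count equals the number of distinct tracks", {
  scene <- generate_scene(quick_params(rng_seed = 13L))
  stack <- section_scene(scene, section_plan())
  marks <- stack_marks(stack)
  expect_identical(length(unique(marks$track_id)), nrow(scene$vesicles))
  # multi-section appearance means more marks than tracks
  expect_gte(nrow(marks), nrow(scene$vesicles))
})

test_that("section loss leaves explicit gaps rather than re-indexing", {
  scene <- generate_scene(quick_params(rng_seed = 2L))
  stack <- section_scene(scene, section_plan(loss_probability = 0.2),
                         rng_seed = 8L)
  s <- stack$sections
  expect_true(any(s$lost))
  expect_identical(s$index, seq_len(nrow(s)))
  expect_true(all(vapply(which(s$lost), function(i) is.null(s$polygons[[i]]) ||
                           length(s$polygons[[i]]) == 0L, TRUE)))
})

test_that("stack JSON serialisation round-trips sections, polygons and marks", {
  scene <- generate_scene(quick_params(total_sv = 30L, rng_seed = 4L))
  stack <- section_scene(scene, section_plan())
  f <- tempfile(fileext = ".json")
  write_stack_json(stack, f)
  back <- read_stack_json(f)
  expect_equal(back$sections$z_lo, stack$sections$z_lo)
  expect_equal(back$sections$thickness, stack$sections$thickness)
  i <- which(vapply(stack$sections$polygons, length, 0L) > 0)[1L]
  expect_equal(back$sections$polygons[[i]][[1L]]$xy,
               stack$sections$polygons[[i]][[1L]]$xy, ignore_attr = TRUE)
  m_old <- stack_marks(stack); m_new <- stack_marks(back)
  expect_equal(m_new$x, m_old$x)
  expect_equal(m_new$measured_diameter, m_old$measured_diameter)
  unlink(f)
})
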
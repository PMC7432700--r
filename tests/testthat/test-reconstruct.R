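# Alignment, Cavalieri volumes and lofted surface models.

test_that("Cavalieri volume of a single square contour is area x thickness", {
  st <- make_stack(0, 55, list(list(poly_entry(square_poly(1000)))))
  expect_equal(cavalieri_volume(st, "bouton"), 0.055)
})

test_that("Cavalieri volume rejects unclosed polygons", {
  bad <- square_poly(1000)[1:4, ]
  st <- make_stack(0, 55, list(list(poly_entry(bad))))
  expect_error(cavalieri_volume(st, "bouton"), "unclosed")
})

test_that("sphere fixtures: Cavalieri within 1%, lofted surface within 2%", {
  set.seed(1)
  st <- sphere_stack(r = 500, dz = 10)
  expect_equal(cavalieri_volume(st, "bouton"), 4 / 3 * pi * 0.5^3,
               tolerance = 0.01)
  loft <- loft_surface(st, "bouton")
  expect_equal(loft$surface_area, 4 * pi * 0.5^2, tolerance = 0.02)
  expect_identical(loft$completeness, "complete")
})

test_that("cylinder loft area matches 2*pi*r*h + 2*pi*r^2 within 1%", {
  st <- cylinder_stack(r = 400, h = 1100, dz = 55)
  loft <- loft_surface(st, "bouton")
  # contours sit at section mid-planes, so the lofted length spans h - dz
  # between first and last mid-plane plus the flat caps
  h_eff <- max(st$sections$z_mid) - min(st$sections$z_mid)
  truth <- (2 * pi * 400 * h_eff + 2 * pi * 400^2) / 1e6
  expect_equal(loft$surface_area, truth, tolerance = 0.01)
})

test_that("mesh volume of the loft agrees with Cavalieri on convex fixtures", {
  set.seed(2)
  st <- sphere_stack(r = 450, dz = 55)
  loft <- loft_surface(st, "bouton")
  expect_equal(loft$mesh_volume, cavalieri_volume(st, "bouton"),
               tolerance = 0.03)
})

test_that("halving the section pitch never worsens the sphere volume error", {
  set.seed(3)
  truth <- 4 / 3 * pi * 0.5^3
  errs <- vapply(c(80, 40, 20, 10), function(dz) {
    abs(cavalieri_volume(sphere_stack(r = 500, dz = dz), "bouton") - truth)
  }, 0)
  expect_true(all(diff(errs) <= 1e-4))
})

test_that("alignment recovers injected per-section shifts within 2 nm RMS", {
  set.seed(7)
  st <- sphere_stack(r = 500, dz = 40)
  n <- nrow(st$sections)
  shifts <- cbind(cumsum(rnorm(n, 0, 15)), cumsum(rnorm(n, 0, 15)))
  shifted <- st
  for (i in seq_len(n)) {
    shifted$sections$polygons[[i]] <- lapply(st$sections$polygons[[i]], function(p) {
      p$xy <- sweep(p$xy, 2L, -shifts[i, ]); p
    })
  }
  shifted$alignment_state <- "raw"
  aligned <- align_stack(shifted)
  trans <- attr(aligned, "applied_translations")
  # recovered translations should undo the injected drift, up to the global
  # reference fixed by the first observed section
  obs <- which(vapply(st$sections$polygons, length, 0L) > 0)
  resid <- sweep((shifts + trans)[obs, , drop = FALSE], 2L,
                 shifts[obs[1L], ] + trans[obs[1L], ])
  rms <- sqrt(mean(resid^2))
  expect_lt(rms, 2)
  expect_identical(aligned$alignment_state, "aligned")
})

test_that("alignment of an already-aligned stack is the identity", {
  set.seed(8)
  st <- sphere_stack(r = 500, dz = 40)
  aligned <- align_stack(st)
  trans <- attr(aligned, "applied_translations")
  expect_lt(max(abs(trans)), 1)
})

test_that("a single shifted section is translated back by the negated shift", {
  set.seed(9)
  st <- sphere_stack(r = 400, dz = 50)
  n <- nrow(st$sections)
  k <- floor(n / 2)
  st$sections$polygons[[k]] <- lapply(st$sections$polygons[[k]], function(p) {
    p$xy <- sweep(p$xy, 2L, -c(100, -40)); p
  })
  st$alignment_state <- "raw"
  aligned <- align_stack(st)
  trans <- attr(aligned, "applied_translations")
  expect_equal(trans[k, ], c(-100, 40), tolerance = 0.5, ignore_attr = TRUE)
  # later sections must not inherit the correction (drift is re-anchored)
  expect_lt(max(abs(trans[n, ])), 1)
})

test_that("rigid whole-stack translation changes no derived quantity", {
  set.seed(10)
  st <- sphere_stack(r = 500, dz = 55)
  v0 <- cavalieri_volume(st, "bouton")
  a0 <- loft_surface(st, "bouton")$surface_area
  shifted <- st
  for (i in seq_len(nrow(st$sections))) {
    shifted$sections$polygons[[i]] <- lapply(st$sections$polygons[[i]], function(p) {
      p$xy <- sweep(p$xy, 2L, -c(5000, -3000)); p
    })
  }
  expect_equal(cavalieri_volume(shifted, "bouton"), v0, tolerance = 1e-9)
  expect_equal(loft_surface(shifted, "bouton")$surface_area, a0,
               tolerance = 1e-3)
})

test_that("alignment errors name the offending section pair", {
  st <- make_stack(0, 55, list(list(poly_entry(circle_poly(200))),
                               list(poly_entry(circle_poly(200, cx = 5000)))))
  st$alignment_state <- "raw"
  expect_error(align_stack(st), "sections 1 and 2")
})

test_that("reconstruct_bouton assembles volume, surface and mito counts", {
  scene <- generate_scene(quick_params(rng_seed = 5L))
  stack <- section_scene(scene, section_plan())
  model <- reconstruct_bouton(stack)
  expect_s3_class(model, "syn_bouton_model")
  expect_equal(model$volume, scene$realized$volume / 1e9, tolerance = 0.05)
  expect_equal(model$surface_area, scene$realized$surface_area / 1e6,
               tolerance = 0.12)
  expect_identical(model$n_mitochondria, length(scene$mitochondria))
  expect_equal(model$mito_volume_fraction,
               scene$realized$mito_volume_fraction, tolerance = 0.25)
})
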
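# PreAZ extraction, PSD estimation, cleft widths, AZ shape classes.

test_that("the apposition predicate is strictly below the threshold", {
  density <- cbind(c(0, 100), c(0, 0))
  pts <- cbind(c(50, 50, 50), c(29, 30, 31))
  expect_identical(within_apposition(pts, density, 30), c(TRUE, FALSE, FALSE))
})

test_that("PreAZ area of a polar-cap annotation matches the cap closed form", {
  st <- cap_stack(r = 500, dz = 10, z_cap = 0, offset = 10)
  model <- reconstruct_bouton(st)
  pre <- extract_preaz(model, threshold = 30)
  cap_true <- 2 * pi * 500 * 500 / 1e6   # hemisphere
  expect_equal(pre$sa_preaz_um2, cap_true, tolerance = 0.03)
  expect_lte(pre$sa_preaz_um2, model$surface_area)
})

test_that("a bouton without density annotation reports zero PreAZ with a warning", {
  set.seed(5)
  st <- sphere_stack(r = 400, dz = 20)
  model <- reconstruct_bouton(st)
  expect_warning(pre <- extract_preaz(model), "no presynaptic density")
  expect_identical(nrow(pre), 0L)
})

test_that("PSD area estimator applies the contour-length ratio exactly", {
  expect_identical(estimate_psd_area(0.2, 300, 200), 0.3)
  expect_identical(estimate_psd_area(0.17, 250, 250), 0.17)
  expect_error(estimate_psd_area(0.2, 300, 0), "l_preaz")
})

test_that("PSD estimator is scale-homogeneous", {
  set.seed(1)
  for (i in 1:20) {
    sa <- runif(1, 0.05, 0.4); lp <- runif(1, 100, 900); lq <- runif(1, 100, 900)
    k <- runif(1, 0.2, 5)
    expect_equal(estimate_psd_area(sa * k^2, lq * k, lp * k),
                 k^2 * estimate_psd_area(sa, lq, lp))
  }
})

test_that("PSD estimate on a parallel-membrane scene is close to ground truth", {
  params <- quick_params(rng_seed = 6L)
  scene <- generate_scene(params)
  stack <- section_scene(scene, section_plan())
  model <- reconstruct_bouton(stack)
  pre <- extract_preaz(model)
  lens <- az_density_lengths(stack)
  est <- estimate_psd_area(pre$sa_preaz_um2[1L],
                           lens$l_psd_nm[1L], lens$l_preaz_nm[1L])
  truth <- scene$az[[1L]]$sa_psd_true / 1e6
  expect_equal(est, truth, tolerance = 0.12)
})

test_that("cleft records average the lateral widths and filter oblique cuts", {
  rec <- measure_cleft(16, 18, 30)
  expect_equal(rec$lateral_mean, 17)
  expect_equal(rec$central, 30)
  expect_true(rec$included)
  expect_message(bad <- measure_cleft(16, 18, 30, perpendicularity_ok = FALSE),
                 "excluded")
  expect_false(bad$included)
  expect_true(is.na(bad$lateral_mean))
})

test_that("stack-level cleft widths recover the configured gap", {
  params <- quick_params(rng_seed = 8L)
  params$cleft <- cleft_spec(lateral_width = 17.24, central_width = 19.05,
                             noise_sd = 0.5)
  scene <- generate_scene(params)
  stack <- section_scene(scene, section_plan())
  cl <- measure_cleft_stack(stack)
  cl <- cl[cl$included, ]
  expect_gt(nrow(cl), 0L)
  expect_equal(mean(cl$lateral_mean), 17.24, tolerance = 0.15)
  expect_equal(mean(cl$central), 19.05, tolerance = 0.15)
})

# planar point-set fixtures for topology classification
disk_pts <- function(n = 4000, r = 250) {
  u <- sqrt(runif(n)) * r; a <- runif(n, 0, 2 * pi)
  cbind(u * cos(a), u * sin(a), 0)
}

test_that("AZ shape classification recognises the four topologies", {
  set.seed(33)
  expect_identical(classify_az_shape(disk_pts()), "macular")
  ann <- disk_pts(6000, 300)
  ann <- ann[sqrt(ann[, 1L]^2 + ann[, 2L]^2) > 170, ]
  expect_identical(classify_az_shape(ann), "ring")
  cshape <- disk_pts(8000, 300)
  rr <- sqrt(cshape[, 1L]^2 + cshape[, 2L]^2)
  tau <- atan2(cshape[, 2L], cshape[, 1L])
  cshape <- cshape[rr > 160 & abs(tau) > pi / 3, ]
  expect_identical(classify_az_shape(cshape), "horseshoe")
  perf <- disk_pts(8000, 300)
  hole <- sqrt((perf[, 1L] - 90)^2 + perf[, 2L]^2) < 60
  expect_identical(classify_az_shape(perf[!hole, ]), "perforated")
  expect_error(classify_az_shape(matrix(numeric(0), 0L, 3L)), "empty")
})

test_that("generator-made horseshoe patches classify as horseshoe", {
  params <- quick_params(rng_seed = 10L, total_sv = 40L)
  params$az_shape <- "horseshoe"
  scene <- generate_scene(params)
  az <- scene$az[[1L]]
  pts <- rbind(az$tri_fine$v1, az$tri_fine$v2, az$tri_fine$v3)
  expect_identical(classify_az_shape(pts), "horseshoe")
})
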
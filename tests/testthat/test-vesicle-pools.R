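# Perimeter computation, pool classification, docked counting, dense-core
# de-duplication.

test_that("perimeter is centre distance minus radius", {
  # one section: density along x axis, a mark at known offset
  dens <- poly_entry(cbind(c(-200, 200), c(0, 0)), label = "preaz_density",
                     az = 1L, closed = FALSE)
  marks <- tibble::tibble(track_id = 1:2,
                          x = c(0, 0), y = c(35, 15),
                          measured_diameter = c(30, 30),
                          dense_core = FALSE, docked = FALSE)
  st <- make_stack(0, 55, list(list(dens)), list(marks))
  rec <- vesicle_perimeter(st)
  expect_equal(rec$center_distance, c(35, 15))
  expect_equal(rec$perimeter_p, c(20, 0))   # 15 - 15 = 0 (tangent)
})

test_that("negative centre distances clamp to a zero perimeter", {
  dens <- poly_entry(cbind(c(-200, 200), c(0, 0)), label = "preaz_density",
                     az = 1L, closed = FALSE)
  marks <- tibble::tibble(track_id = 1L, x = 0, y = 5,
                          measured_diameter = 30, dense_core = FALSE,
                          docked = TRUE)
  st <- make_stack(0, 55, list(list(dens)), list(marks))
  rec <- vesicle_perimeter(st)
  expect_identical(rec$perimeter_p, 0)
})

test_that("perimeters match an exhaustive point-to-segment search", {
  set.seed(21)
  line <- cbind(cumsum(runif(30, 10, 40)) - 300, 60 * sin(seq_len(30) / 4))
  dens <- poly_entry(line, label = "preaz_density", az = 1L, closed = FALSE)
  n <- 200L
  marks <- tibble::tibble(track_id = seq_len(n),
                          x = runif(n, -350, 450), y = runif(n, -300, 300),
                          measured_diameter = runif(n, 30, 40),
                          dense_core = FALSE, docked = FALSE)
  st <- make_stack(0, 55, list(list(dens)), list(marks))
  rec <- vesicle_perimeter(st)
  brute <- vapply(seq_len(n), function(i) {
    dmin <- Inf
    for (k in seq_len(nrow(line) - 1L)) {
      t <- seq(0, 1, length.out = 600L)
      px <- line[k, 1L] + t * diff(line[, 1L])[k]
      py <- line[k, 2L] + t * diff(line[, 2L])[k]
      dmin <- min(dmin, sqrt((px - marks$x[i])^2 + (py - marks$y[i])^2))
    }
    max(dmin - marks$measured_diameter[i] / 2, 0)
  }, 0)
  expect_lt(max(abs(rec$perimeter_p - brute)), 0.5)
})

test_that("marks in sections without density fall back to the cross-section distance", {
  dens <- poly_entry(cbind(c(-200, 200), c(0, 0)), label = "preaz_density",
                     az = 1L, closed = FALSE)
  marks2 <- tibble::tibble(track_id = 2L, x = 0, y = 0,
                           measured_diameter = 30, dense_core = FALSE,
                           docked = FALSE)
  st <- make_stack(0, 55, list(list(dens), list()), list(NULL, marks2))
  rec <- vesicle_perimeter(st)
  expect_identical(rec$method_used, "3d_fallback")
  # axial offset between mid-planes (55) credited the slab half-thickness
  expect_equal(rec$center_distance, 27.5)
})

test_that("pool classification bins by the edge table", {
  recs <- tibble::tibble(perimeter_p = c(5, 15, 100, 250),
                         docked = c(TRUE, FALSE, FALSE, FALSE),
                         dense_core = FALSE)
  pc <- classify_pools(recs)
  expect_identical(pc$n_p10, 1L)
  expect_identical(pc$n_p20, 2L)
  expect_identical(pc$n_intermediate, 0L)
  expect_identical(pc$n_rp, 1L)
  expect_identical(pc$n_resting, 1L)
  expect_identical(pc$n_docked, 1L)
  # boundary cases: 60 belongs to the recycling pool, 200 as well
  pc2 <- classify_pools(tibble::tibble(perimeter_p = c(10, 20, 60, 200, 200.001)))
  expect_identical(pc2$n_p10, 1L)
  expect_identical(pc2$n_p20, 2L)
  expect_identical(pc2$n_rp, 2L)
  expect_identical(pc2$n_resting, 1L)
})

test_that("pool counts conserve records and respect cumulative ordering", {
  set.seed(2)
  for (rep in 1:5) {
    p <- c(runif(300, 0, 400), rep(NA_real_, 3))
    pc <- classify_pools(tibble::tibble(perimeter_p = p))
    expect_identical(pc$n_total + pc$n_excluded, length(p))
    expect_identical(pc$n_p20 + pc$n_intermediate + pc$n_rp + pc$n_resting,
                     pc$n_total)
    expect_lte(pc$n_p10, pc$n_p20)
    # independent one-pass recount
    q <- p[!is.na(p)]
    expect_identical(pc$n_p10, sum(q <= 10))
    expect_identical(pc$n_p20, sum(q <= 20))
    expect_identical(pc$n_resting, sum(q > 200))
  }
  empty <- classify_pools(tibble::tibble(perimeter_p = numeric()))
  expect_identical(empty$n_total, 0L)
  expect_identical(empty$n_resting, 0L)
})

test_that("docked counts come from flags and bound the p10 pool", {
  expect_identical(count_docked(tibble::tibble(perimeter_p = 1:3)), 0L)
  scene <- generate_scene(quick_params(rng_seed = 14L))
  stack <- section_scene(scene, section_plan())
  rec <- vesicle_perimeter(stack, marks = primary_marks(stack_marks(stack)))
  pc <- classify_pools(rec)
  expect_identical(count_docked(rec), scene$realized$n_docked)
  expect_lte(pc$n_docked, pc$n_p10)
  expect_lte(pc$n_p10, pc$n_p20)
})

test_that("dense-core de-duplication keeps the largest-profile mark", {
  marks <- tibble::tibble(
    section_index = c(10L, 11L, 12L, 30L),
    x = c(0, 1, -1, 500), y = c(0, 1, 0, 500),
    measured_diameter = c(40, 48, 44, 70),
    dense_core = TRUE)
  out <- dedup_dense_core(marks)
  expect_identical(nrow(out), 2L)
  expect_identical(out$section_index[out$x < 100], 11L)
  expect_identical(out$measured_diameter[out$x < 100], 48)
  # single mark is untouched
  one <- dedup_dense_core(marks[4L, ])
  expect_identical(nrow(one), 1L)
})

test_that("de-duplicated count equals the ground-truth track count", {
  set.seed(31)
  n_tracks <- 50L
  rows <- list()
  zc <- runif(n_tracks, 0, 5000)
  xc <- runif(n_tracks, 0, 5000); yc <- runif(n_tracks, 0, 5000)
  for (t in seq_len(n_tracks)) {
    sec0 <- floor(zc[t] / 55)
    n_app <- sample(1:3, 1L)
    for (j in seq_len(n_app)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        section_index = sec0 + j - 1L, x = xc[t] + rnorm(1, 0, 2),
        y = yc[t] + rnorm(1, 0, 2),
        measured_diameter = runif(1, 55, 85), dense_core = TRUE)
    }
  }
  marks <- dplyr::bind_rows(rows)
  out <- dedup_dense_core(marks)
  expect_identical(nrow(out), n_tracks)
})
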
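# Planar and mesh geometry primitives.

test_that("polygon area and length match closed forms", {
  sq <- square_poly(1000)
  expect_equal(polygon_area(sq), 1e6)
  expect_equal(polyline_length(sq), 4000)
  circ <- circle_poly(500, n = 2048L)
  expect_equal(polygon_area(circ), pi * 500^2, tolerance = 1e-4)
  expect_equal(polyline_length(circ), 2 * pi * 500, tolerance = 1e-4)
})

test_that("point-to-polyline distance agrees with brute-force search", {
  set.seed(42)
  line <- cbind(cumsum(runif(40, 5, 30)), cumsum(rnorm(40, 0, 15)))
  pts <- cbind(runif(50, -50, 800), runif(50, -120, 120))
  fast <- dist_points_polyline(pts, line)
  # brute force: dense sampling of every segment
  brute <- vapply(seq_len(nrow(pts)), function(i) {
    dmin <- Inf
    for (k in seq_len(nrow(line) - 1L)) {
      t <- seq(0, 1, length.out = 400L)
      px <- line[k, 1L] + t * (line[k + 1L, 1L] - line[k, 1L])
      py <- line[k, 2L] + t * (line[k + 1L, 2L] - line[k, 2L])
      dmin <- min(dmin, sqrt((px - pts[i, 1L])^2 + (py - pts[i, 2L])^2))
    }
    dmin
  }, 0)
  expect_lt(max(abs(fast - brute)), 0.05)
})

test_that("point-to-triangle distance is exact on hand-checkable cases", {
  v1 <- matrix(c(0, 0, 0), 1L); v2 <- matrix(c(10, 0, 0), 1L)
  v3 <- matrix(c(0, 10, 0), 1L)
  # above the interior: perpendicular distance
  expect_equal(dist_point_triangles(c(2, 2, 5), v1, v2, v3), 5)
  # beyond a vertex
  expect_equal(dist_point_triangles(c(-3, -4, 0), v1, v2, v3), 5)
  # beyond an edge
  expect_equal(dist_point_triangles(c(5, -2, 0), v1, v2, v3), 2)
})

test_that("mesh area and volume match closed forms for a sphere", {
  sh <- synmorph:::new_bouton_shape(1, 300, NULL, 0)
  m <- synmorph:::bouton_shape_mesh(sh, 120L, 144L)
  expect_equal(mesh_area(m), 4 * pi * 300^2, tolerance = 2e-3)
  expect_equal(mesh_volume(m), 4 / 3 * pi * 300^3, tolerance = 2e-3)
})

test_that("cross-sections of a spheroid have the analytic radius", {
  sh <- synmorph:::new_bouton_shape(2, 250, NULL, 0)
  for (z in c(-300, 0, 150, 420)) {
    poly <- synmorph:::shape_cross_section(sh, z, max_spacing = 5)
    r_true <- 250 * sqrt(1 - (z / 500)^2)
    expect_equal(max(abs(sqrt(poly[, 1L]^2 + poly[, 2L]^2) - r_true)), 0,
                 tolerance = 0.1)
  }
  expect_null(synmorph:::shape_cross_section(sh, 501, max_spacing = 5))
})
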
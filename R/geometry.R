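#' @importFrom stats rnorm runif sd setNames aggregate
#' @importFrom utils head tail
NULL

# ---- planar polygon / polyline primitives -----------------------------------
# Polygons are n x 2 matrices in nm. Closed polygons repeat the first vertex as
# the last row (documented convention); polylines do not.

#' Signed area of a closed polygon (shoelace)
#'
#' @param xy closed polygon, n x 2 matrix with first row == last row.
#' @return signed area in nm^2 (positive if counter-clockwise).
#' @keywords internal
polygon_area_signed <- function(xy) {
  stopifnot(is.matrix(xy), ncol(xy) == 2L)
  n <- nrow(xy)
  if (n < 4L) return(0)
  x <- xy[, 1L]; y <- xy[, 2L]
  sum(x[-n] * y[-1L] - x[-1L] * y[-n]) / 2
}

#' Absolute area of a closed polygon
#' @inheritParams polygon_area_signed
#' @return area in nm^2.
#' @export
polygon_area <- function(xy) abs(polygon_area_signed(xy))

is_closed_polygon <- function(xy) {
  is.matrix(xy) && nrow(xy) >= 4L &&
    isTRUE(all.equal(xy[1L, ], xy[nrow(xy), ], tolerance = 1e-9,
                     check.attributes = FALSE))
}

#' Length of a polyline (or closed polygon outline)
#' @param xy n x 2 matrix of vertices.
#' @return summed segment length in nm.
#' @export
polyline_length <- function(xy) {
  if (is.null(xy) || nrow(xy) < 2L) return(0)
  d <- diff(xy)
  sum(sqrt(rowSums(d^2)))
}

#' Ensure counter-clockwise orientation of a closed polygon
#' @keywords internal
ensure_ccw <- function(xy) {
  if (polygon_area_signed(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

polygon_centroid <- function(xy) {
  # area-weighted centroid of a closed polygon; falls back to vertex mean
  n <- nrow(xy)
  x <- xy[-n, 1L]; y <- xy[-n, 2L]
  x2 <- xy[-1L, 1L]; y2 <- xy[-1L, 2L]
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(colMeans(xy[-n, , drop = FALSE]))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

#' Resample a closed polygon to n equally spaced vertices
#'
#' Arc-length resampling; the result is again closed (first row repeated last).
#' @param xy closed polygon.
#' @param n number of distinct vertices.
#' @keywords internal
resample_closed <- function(xy, n) {
  stopifnot(is_closed_polygon(xy))
  seg <- sqrt(rowSums(diff(xy)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate polygon with zero perimeter")
  s <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(xy)] <- nrow(xy) - 1L
  frac <- (s - cum[idx]) / pmax(seg[idx], 1e-12)
  pts <- xy[idx, , drop = FALSE] + (xy[idx + 1L, , drop = FALSE] - xy[idx, , drop = FALSE]) * frac
  rbind(pts, pts[1L, , drop = FALSE])
}

#' Minimum distances from points to a polyline
#'
#' Exact point-to-segment distances, vectorised over segments.
#'
#' @param pts m x 2 matrix of query points.
#' @param line n x 2 matrix of polyline vertices (use a closed polygon for an
#'   outline; the repeated vertex is harmless).
#' @return numeric vector of length m (nm).
#' @export
dist_points_polyline <- function(pts, line) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  if (nrow(line) < 2L) {
    d <- sqrt((pts[, 1L] - line[1L, 1L])^2 + (pts[, 2L] - line[1L, 2L])^2)
    return(d)
  }
  a <- line[-nrow(line), , drop = FALSE]
  b <- line[-1L, , drop = FALSE]
  ab <- b - a
  len2 <- pmax(rowSums(ab^2), 1e-12)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    ap1 <- pts[i, 1L] - a[, 1L]
    ap2 <- pts[i, 2L] - a[, 2L]
    t <- pmin(pmax((ap1 * ab[, 1L] + ap2 * ab[, 2L]) / len2, 0), 1)
    dx <- ap1 - t * ab[, 1L]
    dy <- ap2 - t * ab[, 2L]
    out[i] <- sqrt(min(dx * dx + dy * dy))
  }
  out
}

#' Are points strictly inside a closed polygon?
#' @keywords internal
points_in_polygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  mgcv::in.out(poly, pts)
}

# ---- triangle meshes --------------------------------------------------------
# mesh: list(vertices = n x 3, faces = m x 3 integer), nm coordinates.

new_mesh <- function(vertices, faces) {
  list(vertices = vertices, faces = faces)
}

mesh_triangle_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a triangle mesh
#' @param mesh list with `vertices` (n x 3) and `faces` (m x 3).
#' @return area in nm^2.
#' @export
mesh_area <- function(mesh) sum(mesh_triangle_areas(mesh))

#' Volume enclosed by a watertight mesh (divergence theorem)
#' @inheritParams mesh_area
#' @return volume in nm^3 (absolute value).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  abs(sum(p1[, 1L] * (p2[, 2L] * p3[, 3L] - p3[, 2L] * p2[, 3L]) -
          p2[, 1L] * (p1[, 2L] * p3[, 3L] - p3[, 2L] * p1[, 3L]) +
          p3[, 1L] * (p1[, 2L] * p2[, 3L] - p2[, 2L] * p1[, 3L]))) / 6
}

mesh_face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1L], , drop = FALSE] + v[f[, 2L], , drop = FALSE] + v[f[, 3L], , drop = FALSE]) / 3
}

mesh_face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
             a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
             a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  n / pmax(sqrt(rowSums(n^2)), 1e-12)
}

#' Exact minimum distance from one point to a set of triangles
#'
#' Vectorised over triangles (Ericson's region test).
#' @param p length-3 point.
#' @param v1,v2,v3 m x 3 matrices of triangle vertices.
#' @return scalar minimum distance (nm).
#' @keywords internal
dist_point_triangles <- function(p, v1, v2, v3) {
  ab <- v2 - v1; ac <- v3 - v1
  ap <- matrix(p, nrow(v1), 3L, byrow = TRUE) - v1
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- matrix(p, nrow(v1), 3L, byrow = TRUE) - v2
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- matrix(p, nrow(v1), 3L, byrow = TRUE) - v3
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)

  # candidate closest points per region
  close <- v1  # region A
  reg_b <- d3 >= 0 & d4 <= d3
  close[reg_b, ] <- v2[reg_b, , drop = FALSE]
  vc <- d1 * d4 - d3 * d2
  reg_ab <- vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(reg_ab)) {
    t <- d1[reg_ab] / (d1[reg_ab] - d3[reg_ab])
    close[reg_ab, ] <- v1[reg_ab, , drop = FALSE] + t * ab[reg_ab, , drop = FALSE]
  }
  reg_c <- d6 >= 0 & d5 <= d6
  close[reg_c, ] <- v3[reg_c, , drop = FALSE]
  vb <- d5 * d2 - d1 * d6
  reg_ac <- vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(reg_ac)) {
    t <- d2[reg_ac] / (d2[reg_ac] - d6[reg_ac])
    close[reg_ac, ] <- v1[reg_ac, , drop = FALSE] + t * ac[reg_ac, , drop = FALSE]
  }
  va <- d3 * d6 - d5 * d4
  reg_bc <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(reg_bc)) {
    t <- (d4[reg_bc] - d3[reg_bc]) / ((d4[reg_bc] - d3[reg_bc]) + (d5[reg_bc] - d6[reg_bc]))
    close[reg_bc, ] <- v2[reg_bc, , drop = FALSE] +
      t * (v3[reg_bc, , drop = FALSE] - v2[reg_bc, , drop = FALSE])
  }
  interior <- !(reg_b | reg_ab | reg_c | reg_ac | reg_bc) &
    !(d1 <= 0 & d2 <= 0)
  # interior: project onto the plane
  if (any(interior)) {
    denom <- va + vb + vc
    ok <- interior & abs(denom) > 1e-300
    if (any(ok)) {
      v_ <- vb[ok] / denom[ok]
      w_ <- vc[ok] / denom[ok]
      close[ok, ] <- v1[ok, , drop = FALSE] + v_ * ab[ok, , drop = FALSE] +
        w_ * ac[ok, , drop = FALSE]
    }
  }
  dx <- p[1L] - close[, 1L]; dy <- p[2L] - close[, 2L]; dz <- p[3L] - close[, 3L]
  sqrt(min(dx * dx + dy * dy + dz * dz))
}

# ---- deterministic RNG scoping ---------------------------------------------

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so package functions are deterministic
#' without disturbing the caller's random stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
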
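# Star-shaped bouton surface model.
#
# The bouton membrane is a radial surface about its centre:
#   x(u) = r(u) * u,  u on the unit sphere,
# where r(u) is an elongated spheroid radius (long axis along z, emulating an
# axon running through an en passant swelling) modulated by a few smooth
# random bumps. Everything downstream (meshing, planar cross-sections, inside
# tests) derives from r(u), so ground truth and observation stay consistent.

new_bouton_shape <- function(k, scale, bumps, taper = 0, f = 1) {
  structure(list(k = k, f = f, scale = scale, bumps = bumps, taper = taper),
            class = "bouton_shape")
}

# membrane wrinkle field: many smooth radial bumps whose common amplitude is
# solved so the crumpled surface reaches the surface-area target at the
# volume target (real boutons owe their high area/volume ratio to membrane
# irregularity, not to extreme elongation). Bumps avoid the active-zone
# directions so the synaptic apposition stays smooth.
random_bumps <- function(n = 96L, width = 0.18, az_dirs = NULL,
                         az_clear = 0.55) {
  dirs <- matrix(0, 0L, 3L)
  guard <- 0L
  while (nrow(dirs) < n && guard < 60L) {
    guard <- guard + 1L
    u <- matrix(rnorm(3L * 2L * n), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    if (!is.null(az_dirs) && nrow(az_dirs)) {
      ang_min <- apply(acos(pmin(pmax(u %*% t(az_dirs), -1), 1)), 1L, min)
      u <- u[ang_min > az_clear, , drop = FALSE]
    }
    dirs <- rbind(dirs, u)
  }
  dirs <- dirs[seq_len(min(n, nrow(dirs))), , drop = FALSE]
  raw <- rnorm(nrow(dirs))
  raw <- (raw - mean(raw))
  raw <- raw / max(stats::sd(raw), 1e-9)
  list(dirs = dirs, amp = raw, width = width, amp_scale = 0)
}

# radial function: U is n x 3 of unit directions, returns radii (same units as
# scale).
shape_radius <- function(shape, U) {
  if (is.null(dim(U))) U <- matrix(U, ncol = 3L)
  f <- if (is.null(shape$f)) 1 else shape$f
  base <- 1 / sqrt((U[, 1L] / f)^2 + U[, 2L]^2 + (U[, 3L] / shape$k)^2)
  mod <- rep(1, nrow(U))
  b <- shape$bumps
  if (!is.null(b) && length(b$amp) && b$amp_scale != 0) {
    cang <- pmin(pmax(U %*% t(b$dirs), -1), 1)
    ang2 <- acos(cang)^2
    field <- as.vector(exp(-ang2 / (2 * b$width^2)) %*% b$amp) * b$amp_scale
    # outward lobes only (the interior core stays the full spheroid, so
    # organelle packing is unconstrained by the crumpling), damped toward the
    # poles so every horizontal slice stays star-shaped about the axis
    envelope <- (U[, 1L]^2 + U[, 2L]^2)^0.75
    mod <- mod + abs(field) * envelope
  }
  if (shape$taper != 0) mod <- mod * (1 - shape$taper * (U[, 3L] + 1) / 2)
  as.vector(shape$scale * base * pmax(mod, 0.35))
}

# lat-long mesh of the surface. Returns mesh plus the (theta, phi) grid sizes.
bouton_shape_mesh <- function(shape, n_theta = 160L, n_phi = 192L) {
  theta <- seq(0, pi, length.out = n_theta + 1L)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  tg <- rep(theta[c(-1L, -(n_theta + 1L))], each = n_phi)
  pg <- rep(phi, times = n_theta - 1L)
  U <- cbind(sin(tg) * cos(pg), sin(tg) * sin(pg), cos(tg))
  Uall <- rbind(c(0, 0, 1), U, c(0, 0, -1))
  r <- shape_radius(shape, Uall)
  V <- Uall * r
  nv <- nrow(V)
  idx <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L  # ring i, col j
  faces <- vector("list", n_theta)
  # top cap
  j <- seq_len(n_phi)
  faces[[1L]] <- cbind(1L, idx(1L, j), idx(1L, j + 1L))
  # bands
  for (i in seq_len(n_theta - 2L)) {
    a <- idx(i, j); b <- idx(i, j + 1L); c <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    faces[[i + 1L]] <- rbind(cbind(a, c, b), cbind(b, c, d))
  }
  # bottom cap
  faces[[n_theta]] <- cbind(nv, idx(n_theta - 1L, j + 1L), idx(n_theta - 1L, j))
  mesh <- new_mesh(V, do.call(rbind, faces))
  mesh$n_theta <- n_theta; mesh$n_phi <- n_phi
  mesh
}

# Solve elongation k and scale so the meshed shape matches surface-area and
# volume targets. Works on the bump-perturbed shape family directly.
solve_bouton_shape <- function(surface_target, volume_target, bumps,
                               taper = 0, k0 = 1.6, amp0 = 0.5,
                               n_theta = 120L, n_phi = 144L) {
  # cache the unit-sphere grid and the bump field on it: across bisection
  # iterations only the flattening f (and possibly the lobe amplitude) change
  grid_mesh <- bouton_shape_mesh(new_bouton_shape(1, 1, NULL, 0), n_theta, n_phi)
  U <- grid_mesh$vertices / sqrt(rowSums(grid_mesh$vertices^2))
  field0 <- if (length(bumps$amp)) {
    cang <- pmin(pmax(U %*% t(bumps$dirs), -1), 1)
    as.vector(exp(-acos(cang)^2 / (2 * bumps$width^2)) %*% bumps$amp)
  } else rep(0, nrow(U))
  envelope <- (U[, 1L]^2 + U[, 2L]^2)^0.75
  taper_mod <- if (taper != 0) 1 - taper * (U[, 3L] + 1) / 2 else rep(1, nrow(U))
  measure <- function(f, a) {
    base <- 1 / sqrt((U[, 1L] / f)^2 + U[, 2L]^2 + (U[, 3L] / k0)^2)
    r <- base * pmax((1 + a * abs(field0) * envelope) * taper_mod, 0.35)
    msh <- list(vertices = U * r, faces = grid_mesh$faces)
    c(S = mesh_area(msh), V = mesh_volume(msh))
  }
  finish <- function(f, a) {
    sv <- measure(f, a)
    b <- bumps; b$amp_scale <- a
    new_bouton_shape(k0, sqrt(surface_target / sv[["S"]]), b, taper, f = f)
  }
  if (is.null(volume_target)) return(finish(0.5, amp0))
  rho_target <- volume_target / surface_target^1.5
  ratio <- function(f, a) { sv <- measure(f, a); sv[["V"]] / sv[["S"]]^1.5 }
  if (ratio(1, amp0) < rho_target) {
    # rounder than the lobed spheroid: back the lobes off at full girth
    if (ratio(1, 0) < rho_target)
      stop("infeasible shape: volume target too large relative to the ",
           "surface target for this shape family")
    lo <- 0; hi <- amp0
    for (it in 1:30) {
      mid <- (lo + hi) / 2
      if (ratio(1, mid) > rho_target) lo <- mid else hi <- mid
    }
    return(finish(1, (lo + hi) / 2))
  }
  # flatten until the area/volume ratio is met
  lo <- 0.1; hi <- 1
  if (ratio(lo, amp0) > rho_target)
    stop("infeasible shape: volume target too small relative to the surface ",
         "target for this shape family")
  for (it in 1:35) {
    mid <- (lo + hi) / 2
    if (ratio(mid, amp0) > rho_target) hi <- mid else lo <- mid
  }
  finish((lo + hi) / 2, amp0)
}

# planar cross-section at height z (shape centred at origin). Returns a closed
# polygon (first row repeated) with vertex spacing <= max_spacing, or NULL if
# the plane misses the shape.
shape_cross_section <- function(shape, z, max_spacing = 5) {
  r_pole <- shape_radius(shape, matrix(c(0, 0, sign(z + 1e-12)), 1L))
  if (abs(z) >= r_pole * 0.999) return(NULL)
  # initial guess of in-plane radius from the spheroid
  k <- shape$k; s <- shape$scale
  t0 <- s * sqrt(max(1 - (z / (s * k))^2, 1e-6))
  t0 <- max(t0, 1)
  n <- max(64L, ceiling(2 * pi * t0 / max_spacing))
  alpha <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ca <- cos(alpha); sa <- sin(alpha)
  # per-azimuth bisection on g(t) = |(t ca, t sa, z)| - r(direction):
  # negative inside the membrane, positive outside
  gfun <- function(t) {
    nrm <- sqrt(t^2 + z^2)
    U <- cbind(t * ca, t * sa, rep(z, n)) / nrm
    nrm - shape_radius(shape, U)
  }
  lo <- rep(1e-6, n); hi <- rep(shape$scale * 2.5, n)
  if (any(gfun(lo) >= 0)) return(NULL)  # slice centre outside the body
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    g <- gfun(mid)
    neg <- g < 0
    lo[neg] <- mid[neg]; hi[!neg] <- mid[!neg]
  }
  t <- (lo + hi) / 2
  xy <- cbind(t * ca, t * sa)
  rbind(xy, xy[1L, , drop = FALSE])
}

# strict-ish inside test; tol > 0 admits points within tol outside the radial
# surface.
inside_shape <- function(shape, pts, tol = 0) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  nrm <- sqrt(rowSums(pts^2))
  out <- logical(nrow(pts))
  nz <- nrm > 1e-9
  if (any(!nz)) out[!nz] <- TRUE
  if (any(nz)) {
    U <- pts[nz, , drop = FALSE] / nrm[nz]
    out[nz] <- nrm[nz] <= shape_radius(shape, U) + tol
  }
  out
}

# outward unit normal at surface points, by finite differences of
# F(x) = |x| - r(x/|x|).
shape_normal <- function(shape, pts, h = 1) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  Fv <- function(p) {
    nrm <- sqrt(rowSums(p^2))
    nrm - shape_radius(shape, p / nrm)
  }
  n <- nrow(pts)
  g <- matrix(0, n, 3L)
  for (d in 1:3) {
    e <- matrix(0, n, 3L); e[, d] <- h
    g[, d] <- (Fv(pts + e) - Fv(pts - e)) / (2 * h)
  }
  g / pmax(sqrt(rowSums(g^2)), 1e-12)
}
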
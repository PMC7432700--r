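# Ground-truth scene generation: bouton surface, active-zone patches,
# mitochondria and vesicle complement with exact per-bin pool counts.

# ---- active-zone patches ----------------------------------------------------

az_mask <- function(az, pts) {
  # pts: n x 3 points on (or very near) the membrane surface
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  v <- sweep(pts, 2L, az$x0)
  d <- sqrt(rowSums(v^2))
  s <- d / az$rho
  keep <- s <= 1
  if (az$shape_class %in% c("ring", "horseshoe")) keep <- keep & s >= 0.55
  if (az$shape_class == "horseshoe") {
    w1 <- v %*% az$e1; w2 <- v %*% az$e2
    tau <- atan2(w2, w1)
    dtau <- abs(((tau - az$tau0 + pi) %% (2 * pi)) - pi)
    keep <- keep & dtau > (pi / 3)   # 120 degree opening
  }
  if (az$shape_class == "perforated") {
    w <- cbind(v %*% az$e1, v %*% az$e2) / az$rho
    for (i in seq_len(nrow(az$holes))) {
      keep <- keep & sqrt((w[, 1L] - az$holes[i, 1L])^2 +
                          (w[, 2L] - az$holes[i, 2L])^2) > az$hole_radius
    }
  }
  as.vector(keep)
}

make_az_patch <- function(shape, mesh, centroids, areas, index, x0, area_target,
                          shape_class, cleft, claimed = NULL,
                          coarse = NULL) {
  n0 <- as.vector(shape_normal(shape, matrix(x0, 1L)))
  e1 <- c(-n0[2L], n0[1L], 0)
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(1, 0, 0)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n0[2L] * e1[3L] - n0[3L] * e1[2L],
          n0[3L] * e1[1L] - n0[1L] * e1[3L],
          n0[1L] * e1[2L] - n0[2L] * e1[1L])
  az <- list(index = index, x0 = x0, n0 = n0, e1 = e1, e2 = e2,
             shape_class = shape_class, tau0 = 0,
             holes = rbind(c(0, 0.45), c(0, -0.45)), hole_radius = 0.2,
             rho = 1)
  # solve rho so the masked patch area hits the target (faces claimed by an
  # earlier, lower-index patch are never re-used)
  free <- if (is.null(claimed)) rep(TRUE, nrow(centroids)) else !claimed
  lo <- sqrt(area_target / pi) * 0.4
  hi <- sqrt(area_target / pi) * 6
  for (it in 1:45) {
    az$rho <- (lo + hi) / 2
    a <- sum(areas[az_mask(az, centroids) & free])
    if (abs(a - area_target) / area_target < 0.003) break
    if (a < area_target) lo <- az$rho else hi <- az$rho
  }
  face_in <- which(az_mask(az, centroids) & free)
  if (!length(face_in)) stop("active-zone patch construction failed (empty patch)")
  az$faces <- face_in
  f <- mesh$faces[face_in, , drop = FALSE]
  az$tri_fine <- list(v1 = mesh$vertices[f[, 1L], , drop = FALSE],
                      v2 = mesh$vertices[f[, 2L], , drop = FALSE],
                      v3 = mesh$vertices[f[, 3L], , drop = FALSE])
  az$areas <- areas[face_in]
  az$sa_preaz_true <- sum(az$areas)
  fine_cent <- centroids[face_in, , drop = FALSE]
  s_cent <- sqrt(rowSums(sweep(fine_cent, 2L, x0)^2)) / az$rho
  bf <- which(s_cent >= stats::quantile(s_cent, 0.85))
  az$boundary_faces <- if (length(bf)) bf else seq_along(az$areas)
  # distance queries run against a coarser triangulation of the same smooth
  # patch (chordal deviation well below 1 nm at these curvatures)
  if (is.null(coarse)) coarse <- mesh
  cc <- mesh_face_centroids(coarse)
  cin <- which(az_mask(az, cc))
  if (!length(cin)) cin <- which.min(rowSums(sweep(cc, 2L, x0)^2))
  fc <- coarse$faces[cin, , drop = FALSE]
  az$tri <- list(v1 = coarse$vertices[fc[, 1L], , drop = FALSE],
                 v2 = coarse$vertices[fc[, 2L], , drop = FALSE],
                 v3 = coarse$vertices[fc[, 3L], , drop = FALSE])
  az$centroids <- cc[cin, , drop = FALSE]
  e <- rbind(az$tri$v2 - az$tri$v1, az$tri$v3 - az$tri$v2, az$tri$v1 - az$tri$v3)
  az$h_cloud <- 0.7 * sqrt(max(rowSums(e^2)))
  # parallel postsynaptic membrane: patch vertices offset outward by the cleft
  # gap field (central width at the patch centre, lateral width at the rim)
  vid <- sort(unique(as.vector(f)))
  vmap <- match(as.vector(f), vid)
  pv <- mesh$vertices[vid, , drop = FALSE]
  s <- pmin(sqrt(rowSums(sweep(pv, 2L, x0)^2)) / az$rho, 1)
  gap <- cleft$central_width + (cleft$lateral_width - cleft$central_width) * s
  if (cleft$noise_sd > 0) gap <- gap + rnorm(length(gap), 0, cleft$noise_sd)
  nrm <- shape_normal(shape, pv)
  pv_off <- pv + nrm * gap
  psd_faces <- matrix(vmap, ncol = 3L)
  az$psd_mesh <- new_mesh(pv_off, psd_faces)
  az$gap <- list(central = cleft$central_width, lateral = cleft$lateral_width,
                 noise_sd = cleft$noise_sd)
  az$sa_psd_true <- mesh_area(az$psd_mesh)
  az
}

# pick well-separated active-zone directions (unit vectors; the bump field
# is kept clear of them so the synaptic apposition stays smooth)
draw_az_dirs <- function(n_az) {
  # appositions sit on the flat faces of the bouton (normals near the +/- x
  # axis), which also keeps them perpendicular to the cutting plane
  signs <- rep(c(1, -1), length.out = n_az)[sample.int(n_az)]
  a <- runif(n_az, 0.75, 0.97)
  psi <- runif(n_az, -0.5, 0.5)
  b <- sqrt(1 - a^2)
  cbind(signs * a, b * cos(psi), b * sin(psi))
}

place_az_patches <- function(shape, mesh, params, az_dirs) {
  centroids <- mesh_face_centroids(mesh)
  areas <- mesh_triangle_areas(mesh)
  coarse <- bouton_shape_mesh(shape, 84L, 100L)
  claimed <- rep(FALSE, nrow(centroids))
  azs <- vector("list", params$n_az)
  for (k in seq_len(params$n_az)) {
    u <- az_dirs[k, ]
    x0 <- u * shape_radius(shape, matrix(u, 1L))
    azs[[k]] <- make_az_patch(shape, mesh, centroids, areas, k, x0,
                              params$az_area_targets[k], params$az_shape[k],
                              params$cleft, claimed = claimed, coarse = coarse)
    claimed[azs[[k]]$faces] <- TRUE
  }
  azs
}

# ---- distances to the nearest active-zone patch ----------------------------

# fast approximate distances (to patch face centroids); P is n x 3
az_cloud_dist <- function(P, azs) {
  n <- nrow(P)
  best <- rep(Inf, n); arg <- rep(1L, n)
  rp2 <- rowSums(P^2)
  for (az in azs) {
    C <- az$centroids
    d2 <- -2 * tcrossprod(P, C)
    d2 <- d2 + rp2
    rc2 <- rowSums(C^2)
    dm <- d2[, 1L] + rc2[1L]
    for (j in seq_len(ncol(d2))[-1L]) {
      cj <- d2[, j] + rc2[j]
      lt <- cj < dm
      dm[lt] <- cj[lt]
    }
    dm <- sqrt(pmax(dm, 0))
    upd <- dm < best
    best[upd] <- dm[upd]; arg[upd] <- az$index
  }
  list(dist = best, az = arg)
}

# exact distance from one point to the triangulated patches
az_exact_dist <- function(p, azs) {
  best <- Inf; arg <- 1L
  for (az in azs) {
    d <- dist_point_triangles(p, az$tri$v1, az$tri$v2, az$tri$v3)
    if (d < best - 1e-9) { best <- d; arg <- az$index }
  }
  list(dist = best, az = arg)
}

# ---- mitochondria -----------------------------------------------------------

inside_mitos <- function(pts, mitos, margin = 0) {
  if (!length(mitos)) return(rep(FALSE, nrow(pts)))
  hit <- rep(FALSE, nrow(pts))
  for (m in mitos) {
    q <- sweep(pts, 2L, m$center)
    hit <- hit | (q[, 1L]^2 / (m$semi[1L] + margin)^2 +
                  q[, 2L]^2 / (m$semi[2L] + margin)^2 +
                  q[, 3L]^2 / (m$semi[3L] + margin)^2) <= 1
  }
  hit
}

place_mitochondria <- function(shape, mesh, params, volume_true, azs = list()) {
  n <- params$n_mitochondria
  frac <- params$mito_volume_fraction_target
  if (n == 0L || frac <= 0) return(list())
  # z windows under each active zone whose core should stay free for the
  # near-AZ vesicle pools
  az_windows <- lapply(azs, function(a) a$x0[3L] + c(-1, 1) * 0.8 * a$rho)
  z_ext <- max(mesh$vertices[, 3L])
  xsec_minmax <- function(z) {
    p <- shape_cross_section(shape, z, max_spacing = 30)
    if (is.null(p)) return(c(0, 0))
    rr <- sqrt(p[, 1L]^2 + p[, 2L]^2)
    c(min(rr), max(rr))
  }
  sp_dirs <- {
    th <- seq(0, pi, length.out = 7L)[-c(1L, 7L)]
    ph <- seq(0, 2 * pi, length.out = 13L)[-13L]
    g <- expand.grid(th = th, ph = ph)
    rbind(cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th)),
          c(0, 0, 1), c(0, 0, -1))
  }
  mito_contained <- function(center, semi, margin = 5) {
    pts <- sweep(sp_dirs %*% diag(semi), 2L, -center)
    all(inside_shape(shape, pts, tol = -margin))
  }
  vols <- rep(volume_true * frac / n, n)
  jit <- exp(runif(n, -0.15, 0.15)); vols <- vols * (sum(vols) / sum(vols * jit)) * jit
  gap <- 60
  # mitochondria are slabs matched to the flattened bouton: thin along x,
  # spread along the wide in-plane axis y and along z, stacked in z within
  # up to three y-lanes
  xsec_extents <- function(z) {
    p <- shape_cross_section(shape, z, max_spacing = 30)
    if (is.null(p)) return(c(0, 0))
    c(min(abs(p[abs(p[, 2L]) < 0.25 * max(abs(p[, 2L])) + 1, 1L]), Inf),
      max(abs(p[, 2L])))
  }
  # guaranteed (base-spheroid) half-width along y at height z; lobes only
  # add material, so lane offsets anchored to this never overshoot
  y_base <- function(z) {
    shape$scale * sqrt(max(1 - (z / (shape$k * shape$scale))^2, 0))
  }
  fit_at <- function(front, sgn, v, yc_frac, ry_capf) {
    mm <- xsec_extents(sgn * (front + 50))
    if (!is.finite(mm[1L]) || mm[1L] <= 0) return(NULL)
    rx <- 0.62 * mm[1L]
    for (shrink in 1:7) {
      if (rx < 22) return(NULL)
      yb <- y_base(front + 50)
      ryz <- sqrt(v / (4 / 3 * pi * rx))
      ry <- min(ryz, ry_capf * yb)
      rz <- v / (4 / 3 * pi * rx * ry)
      # if the slot is z-limited, spread further along y instead
      rz_max <- (0.9 * z_ext - front) / 2 - 5
      if (rz > rz_max) {
        if (rz_max < 30) return(NULL)
        rz <- rz_max
        ry <- v / (4 / 3 * pi * rx * rz)
        if (ry > ry_capf * yb) return(NULL)
      }
      ctr <- front + rz
      yc <- yc_frac * y_base(ctr + 0.5 * rz)
      if (mito_contained(c(0, yc, sgn * ctr), c(rx, ry, rz)))
        return(list(ctr = ctr, yc = yc, semi = c(rx, ry, rz)))
      rx <- rx * 0.85
    }
    NULL
  }
  overlapping_window <- function(ctr, cz, sgn) {
    for (k in seq_along(az_windows)) {
      w <- az_windows[[k]]
      if (sgn * ctr + cz > w[1L] && sgn * ctr - cz < w[2L]) return(k)
    }
    0L
  }
  lanes <- data.frame(yc = c(0, 0.5, -0.5), cap = c(0.7, 0.38, 0.38))
  frontier <- matrix(30, 2L, nrow(lanes),
                     dimnames = list(c("R", "L"), NULL))
  mitos <- vector("list", n)
  carry <- 0
  for (i in seq_len(n)) {
    v_i <- vols[i] + carry
    fa <- NULL; side <- NA; v_placed <- v_i
    # try the full volume, then progressively smaller slabs, carrying the
    # unplaced remainder to the next mitochondrion
    for (fr in c(1, 0.85, 0.7, 0.55, 0.4)) {
      v_try <- v_i * fr
      ord <- order(as.vector(frontier))
      for (o in ord) {
        side_o <- c("R", "L")[(o - 1L) %% 2L + 1L]
        lane <- (o - 1L) %/% 2L + 1L
        sgn <- if (side_o == "R") 1 else -1
        fa <- fit_at(frontier[side_o, lane], sgn, v_try,
                     lanes$yc[lane], lanes$cap[lane])
        if (!is.null(fa)) { side <- side_o; v_placed <- v_try; break }
      }
      if (!is.null(fa)) break
    }
    if (is.null(fa))
      stop("infeasible packing: mitochondria volume target ",
           "(mito_volume_fraction_target x bouton volume) does not fit the ",
           "bouton; reduce the fraction or the mitochondrion count")
    carry <- v_i - v_placed
    sgn <- if (side == "R") 1 else -1
    # (active zones sit on the flat +/- x faces; the thin x profile of the
    # slab leaves the subsynaptic space open)
    mitos[[i]] <- list(center = c(0, fa$yc, sgn * fa$ctr), semi = fa$semi)
    frontier[side, lane] <- fa$ctr + fa$semi[3L] + gap
  }
  if (carry > 0.015 * volume_true)
    stop("infeasible packing: mitochondria volume target ",
         "(mito_volume_fraction_target x bouton volume) does not fit the ",
         "bouton; reduce the fraction or the mitochondrion count")
  mitos
}

# ---- vesicles ---------------------------------------------------------------

POOL_LEVELS <- c("RRP_p10", "RRP_p10_20", "intermediate_20_60",
                 "RP_60_200", "resting_gt200")

# does a whole sphere fit inside the membrane? centre plus six axis-offset
# surface points must lie inside (adequate for wrinkle valleys wider than a
# vesicle); vectorised over candidates
spheres_inside <- function(shape, P, r, tol = 0) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 3L)
  offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  ok <- rep(TRUE, nrow(P))
  for (i in seq_len(nrow(offs))) {
    pts <- P + outer(r, offs[i, ])
    ok <- ok & inside_shape(shape, pts, tol = tol)
  }
  ok
}

# proposal distance ranges per bin (0.5 nm guard bands at the edges; the bins
# themselves are {<=10, (10,20], (20,60), [60,200], >200})
.bin_ranges <- list(RRP_p10 = c(0.5, 9.5), RRP_p10_20 = c(10.5, 19.5),
                    intermediate_20_60 = c(21, 59), RP_60_200 = c(61, 199))

bin_ok <- function(pool, p) {
  switch(pool,
         RRP_p10 = p >= 0 & p <= 10,
         RRP_p10_20 = p > 10 & p <= 20,
         intermediate_20_60 = p > 20 & p < 60,
         RP_60_200 = p >= 60 & p <= 200,
         resting_gt200 = p > 200)
}

place_vesicles <- function(shape, mesh, azs, mitos, params) {
  counts <- pool_counts_from_spec(params$pools, params$total_sv)
  n_docked <- as.integer(round(params$pools$docked_fraction * counts[["RRP_p10"]]))
  r_lo <- params$sv_diameter_range[1L] / 2
  r_hi <- params$sv_diameter_range[2L] / 2
  overlap_tol <- 2
  z_ext <- max(mesh$vertices[, 3L])
  x_max <- max(abs(mesh$vertices[, 1L])) + 5
  y_max <- max(abs(mesh$vertices[, 2L])) + 5
  rec <- list()
  centers <- matrix(numeric(0), 0L, 3L); radii <- numeric(0)
  accept <- function(center, r, pool, docked, dense_core, p, az) {
    rec[[length(rec) + 1L]] <<- list(x = center[1L], y = center[2L],
                                     z = center[3L], radius = r, pool = pool,
                                     docked = docked, dense_core = dense_core,
                                     p_true = p, az = az)
    centers <<- rbind(centers, center); radii <<- c(radii, r)
  }
  clear_of_others <- function(center, r) {
    if (!length(radii)) return(TRUE)
    dx <- centers[, 1L] - center[1L]; dy <- centers[, 2L] - center[2L]
    dz <- centers[, 3L] - center[3L]
    all(dx * dx + dy * dy + dz * dz >= (radii + r - overlap_tol)^2)
  }
  h_cloud <- if (length(azs)) max(vapply(azs, function(a) a$h_cloud, 0)) else 0
  empty_out <- function() {
    tibble::tibble(track_id = integer(), x = numeric(), y = numeric(),
                   z = numeric(), radius = numeric(), pool = character(),
                   docked = logical(), dense_core = logical(),
                   p_true = numeric(), az = integer())
  }
  finish <- function() {
    if (!length(rec)) return(empty_out())
    out <- dplyr::bind_rows(lapply(rec, tibble::as_tibble))
    out$track_id <- seq_len(nrow(out))
    dplyr::relocate(out, track_id)
  }

  # -- dense-core vesicles: few, large, far from the AZ -----------------------
  if (params$n_dense_core > 0L) {
    placed <- 0L
    for (batch in 1:20) {
      if (placed >= params$n_dense_core) break
      m <- 400L
      Pd <- cbind(runif(m, -x_max, x_max), runif(m, -y_max, y_max),
                  runif(m, -z_ext, z_ext))
      rd <- runif(m, 70, 90) / 2
      keep <- spheres_inside(shape, Pd, rd, tol = 0)
      keep[keep] <- !inside_mitos(Pd[keep, , drop = FALSE], mitos,
                                  margin = max(rd))
      if (!any(keep)) next
      Pd <- Pd[keep, , drop = FALSE]; rd <- rd[keep]
      azi <- rep(NA_integer_, nrow(Pd))
      if (length(azs)) {
        cd <- az_cloud_dist(Pd, azs)
        far <- cd$dist - rd > 100 + h_cloud
        Pd <- Pd[far, , drop = FALSE]; rd <- rd[far]; azi <- cd$az[far]
      }
      for (i in seq_len(nrow(Pd))) {
        if (placed >= params$n_dense_core) break
        if (!clear_of_others(Pd[i, ], rd[i])) next
        dc <- vapply(rec, function(x) isTRUE(x$dense_core), TRUE)
        if (any(dc)) {
          cc <- centers[dc, , drop = FALSE]
          if (min(sqrt(rowSums(sweep(cc, 2L, Pd[i, ])^2))) < 250) next
        }
        accept(Pd[i, ], rd[i], NA_character_, FALSE, TRUE, NA_real_, azi[i])
        placed <- placed + 1L
      }
    }
    if (placed < params$n_dense_core)
      stop("infeasible packing: could not place dense-core vesicles")
  }

  if (params$total_sv == 0L) return(finish())
  if (!length(azs)) stop("cannot place vesicle pools without an active zone")

  # -- docked vesicles: in membrane contact on the patch (p = 0) --------------
  az_pick_weights <- vapply(azs, function(a) a$sa_preaz_true, 0)
  if (n_docked > 0L) {
    for (i in seq_len(n_docked)) {
      done <- FALSE
      for (attempt in 1:600) {
        k <- if (length(azs) == 1L) 1L else
          sample.int(length(azs), 1L, prob = az_pick_weights)
        az <- azs[[k]]
        fi <- sample.int(length(az$areas), 1L, prob = az$areas)
        b <- runif(2); if (sum(b) > 1) b <- 1 - b
        pt <- az$tri_fine$v1[fi, ] +
          b[1L] * (az$tri_fine$v2[fi, ] - az$tri_fine$v1[fi, ]) +
          b[2L] * (az$tri_fine$v3[fi, ] - az$tri_fine$v1[fi, ])
        r <- runif(1, r_lo, r_hi)
        nrm <- as.vector(shape_normal(shape, matrix(pt, 1L)))
        ctr <- pt - nrm * r
        ex <- az_exact_dist(ctr, azs)
        if (abs(ex$dist - r) > 1) next
        if (!inside_shape(shape, matrix(ctr, 1L), tol = r)) next
        if (inside_mitos(matrix(ctr, 1L), mitos, margin = r)) next
        if (!clear_of_others(ctr, r)) next
        accept(ctr, r, "RRP_p10", TRUE, FALSE, 0, ex$az)
        done <- TRUE
        break
      }
      if (!done)
        stop("infeasible packing: could not place docked vesicles ",
             "(active-zone surface too crowded)")
    }
  }

  # -- all remaining pools: jittered close-packed lattice sites ---------------
  # spacing keyed to the smallest diameter; per-site radius caps enforce
  # exact non-overlap against already-placed neighbours. If a marginally
  # infeasible draw exhausts a pool, the whole lattice fill is retried with a
  # fresh lattice origin.
  jit_amp <- 1.0
  a_sp <- 2 * r_lo + overlap_tol + 2
  dz_l <- a_sp * sqrt(2 / 3); dy_l <- a_sp * sqrt(3) / 2
  snap_rec <- rec; snap_centers <- centers; snap_radii <- radii
  last_err <- NULL
  done_fill <- FALSE
  for (attempt_fill in 1:3) {
    rec <- snap_rec; centers <- snap_centers; radii <- snap_radii
    origin <- runif(3, 0, a_sp)
    res <- tryCatch({
      zs <- seq(-z_ext, z_ext, by = dz_l) + origin[3L] - a_sp / 2
      sites <- list()
      for (li in seq_along(zs)) {
        ys <- seq(-y_max, y_max, by = dy_l) + origin[2L] - a_sp / 2
        y_off <- (li %% 3L) * dy_l / 3
        for (yi in seq_along(ys)) {
          x_off <- ((yi + li) %% 2L) * a_sp / 2
          xs <- seq(-x_max, x_max, by = a_sp) + x_off + origin[1L] - a_sp / 2
          sites[[length(sites) + 1L]] <- cbind(xs, ys[yi] + y_off, zs[li])
        }
      }
      P <- do.call(rbind, sites)
      dimnames(P) <- NULL
      P <- P + matrix(runif(length(P), -jit_amp, jit_amp), nrow(P), 3L)
      keep <- spheres_inside(shape, P, rep(r_lo, nrow(P)), tol = 0)
      keep[keep] <- !inside_mitos(P[keep, , drop = FALSE], mitos, margin = r_lo)
      P <- P[keep, , drop = FALSE]
      if (!nrow(P)) stop("infeasible packing: no lattice sites inside the bouton")
      fits_hi <- spheres_inside(shape, P, rep(r_hi, nrow(P)), tol = 2)
      fits_hi[fits_hi] <- !inside_mitos(P[fits_hi, , drop = FALSE], mitos,
                                        margin = r_hi)
      site_cap <- function(i) {
        if (!length(radii)) return(r_hi)
        dx <- centers[, 1L] - P[i, 1L]; dy <- centers[, 2L] - P[i, 2L]
        dz <- centers[, 3L] - P[i, 3L]
        min(r_hi, sqrt(dx * dx + dy * dy + dz * dz) - radii + overlap_tol - 0.25)
      }
      cd <- az_cloud_dist(P, azs)
      d_site <- cd$dist; az_site <- cd$az
      exact_done <- rep(FALSE, nrow(P))
      refine <- which(d_site < 230 + r_hi + h_cloud)
      for (i in refine) {
        ex <- az_exact_dist(P[i, ], azs)
        d_site[i] <- ex$dist; az_site[i] <- ex$az; exact_done[i] <- TRUE
      }
      used <- rep(FALSE, nrow(P))
      guards <- list(RRP_p10 = c(0.5, 9.5), RRP_p10_20 = c(10.5, 19.5),
                     intermediate_20_60 = c(21, 59), RP_60_200 = c(61, 199))
      take_bin <- function(pool, n_needed) {
        if (n_needed <= 0L) return(invisible(NULL))
        g <- guards[[pool]]
        r_min_feas <- pmax(r_lo, d_site - g[2L])
        r_max_feas <- pmin(r_hi, d_site - g[1L])
        elig <- which(!used & exact_done & r_min_feas <= r_max_feas)
        if (length(elig) < n_needed)
          stop("infeasible packing: only ", length(elig), " candidate sites ",
               "for ", n_needed, " vesicles in pool '", pool, "'")
        elig <- elig[sample.int(length(elig))]
        placed <- 0L
        for (i in elig) {
          if (placed >= n_needed) break
          hi_i <- min(r_max_feas[i], site_cap(i))
          if (hi_i < r_min_feas[i]) next
          r <- runif(1, r_min_feas[i], hi_i)
          if (!fits_hi[i]) {
            if (!spheres_inside(shape, P[i, , drop = FALSE], r, tol = 2)) next
            if (inside_mitos(P[i, , drop = FALSE], mitos, margin = r)) next
          }
          p_v <- d_site[i] - r
          if (!bin_ok(pool, p_v)) next
          used[i] <<- TRUE
          accept(P[i, ], r, pool, FALSE, FALSE, p_v, az_site[i])
          placed <- placed + 1L
        }
        if (placed < n_needed)
          stop("infeasible packing: only ", placed, " of ", n_needed,
               " vesicles fit in pool '", pool,
               "' (active-zone shell too small for total_sv = ",
               params$total_sv, ")")
      }
      take_bin("RRP_p10", counts[["RRP_p10"]] - n_docked)
      take_bin("RRP_p10_20", counts[["RRP_p10_20"]])
      take_bin("intermediate_20_60", counts[["intermediate_20_60"]])
      take_bin("RP_60_200", counts[["RP_60_200"]])
      # resting pool: any site provably beyond 200 nm
      n_rest <- counts[["resting_gt200"]]
      if (n_rest > 0L) {
        # the provable distance bound also caps the admissible radius, so
        # sites in the band just beyond 200 nm remain usable with smaller
        # vesicles
        d_lb <- ifelse(exact_done, d_site, d_site - h_cloud)
        r_margin <- d_lb - 201.5
        margin_ok <- r_margin >= r_lo
        elig <- which(!used & margin_ok)
        if (length(elig) < n_rest)
          stop("infeasible packing: only ", length(elig), " candidate sites ",
               "for ", n_rest, " resting-pool vesicles")
        elig <- elig[sample.int(length(elig))]
        crowded <- length(elig) < 1.3 * n_rest
        placed <- 0L
        for (i in elig) {
          if (placed >= n_rest) break
          hi_i <- min(site_cap(i), r_margin[i], r_hi)
          if (hi_i < r_lo) next
          if (crowded) hi_i <- min(hi_i, r_lo + 0.45 * (r_hi - r_lo))
          r <- runif(1, r_lo, hi_i)
          if (!fits_hi[i]) {
            if (!spheres_inside(shape, P[i, , drop = FALSE], r, tol = 2)) next
            if (inside_mitos(P[i, , drop = FALSE], mitos, margin = r)) next
          }
          used[i] <- TRUE
          accept(P[i, ], r, "resting_gt200", FALSE, FALSE, d_site[i] - r,
                 az_site[i])
          placed <- placed + 1L
        }
        if (placed < n_rest)
          stop("infeasible packing: only ", placed, " of ", n_rest,
               " resting-pool vesicles fit (total_sv too large for the ",
               "bouton volume)")
      }
      TRUE
    }, error = function(e) e)
    if (isTRUE(res)) { done_fill <- TRUE; break }
    last_err <- res
  }
  if (!done_fill) stop(last_err)
  finish()
}

# ---- scene ------------------------------------------------------------------

#' Generate a ground-truth synthetic synaptic-bouton scene
#'
#' Builds a star-shaped bouton membrane matching the surface-area and volume
#' targets, places active-zone patches with a parallel postsynaptic membrane
#' across the cleft, packs mitochondria to the requested volume fraction, and
#' places the vesicle complement so that every perimeter bin holds exactly its
#' configured integer count (perimeters measured as exact 3D distance to the
#' triangulated presynaptic density patch minus the vesicle radius).
#'
#' @param params a [scene_params()] object.
#' @return a `syn_scene` list: bouton `mesh` and analytic `shape`, `az`
#'   patches, `target_surfaces`, `mitochondria`, the ground-truth `vesicles`
#'   tibble, `realized` quantities and `params`.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  # the stochastic construction occasionally draws a geometry in which the
  # dense pools cannot be packed; retry with fresh draws (deterministically
  # derived from the scene seed) before declaring the configuration
  # infeasible
  last_err <- NULL
  for (build_attempt in seq_len(5L)) {
    seed_i <- as.integer((as.double(params$rng_seed) * 7L + 1000003L *
                            (build_attempt - 1L)) %% 2147483647L)
    out <- tryCatch(generate_scene_once(params, seed_i),
                    error = function(e) e)
    if (!inherits(out, "error")) return(out)
    if (!grepl("infeasible|could not place", conditionMessage(out)))
      stop(out)
    last_err <- out
  }
  stop(last_err)
}

generate_scene_once <- function(params, seed_i) {
  with_seed(seed_i, {
    taper <- if (params$bouton_kind == "end_terminal") 0.15 else 0
    k0 <- if (params$bouton_kind == "end_terminal") 1.2 else 1.6
    az_dirs <- draw_az_dirs(params$n_az)
    bumps <- random_bumps(40L, width = 0.25, az_dirs = az_dirs, az_clear = 0.6)
    shape <- solve_bouton_shape(params$bouton_surface_area_target,
                                params$bouton_volume_target, bumps, taper,
                                k0 = k0)
    mesh <- bouton_shape_mesh(shape, n_theta = 160L, n_phi = 192L)
    surface_true <- mesh_area(mesh)
    volume_true <- mesh_volume(mesh)
    azs <- place_az_patches(shape, mesh, params, az_dirs)
    mitos <- place_mitochondria(shape, mesh, params, volume_true, azs)
    vesicles <- place_vesicles(shape, mesh, azs, mitos, params)
    targets <- lapply(azs, function(az) {
      R_t <- 300
      list(center = az$x0 + az$n0 * (az$gap$central + R_t), radius = R_t,
           kind = params$target_kind)
    })
    realized <- list(
      surface_area = surface_true,
      volume = volume_true,
      az_areas = vapply(azs, function(a) a$sa_preaz_true, 0),
      psd_areas = vapply(azs, function(a) a$sa_psd_true, 0),
      mito_volume_fraction =
        if (length(mitos)) sum(vapply(mitos, function(m) 4 / 3 * pi * prod(m$semi), 0)) /
          volume_true else 0,
      pool_counts = {
        sv <- vesicles[!vesicles$dense_core & !is.na(vesicles$pool), ]
        cnt <- table(factor(sv$pool, levels = POOL_LEVELS))
        stats::setNames(as.integer(cnt), POOL_LEVELS)
      },
      n_docked = sum(vesicles$docked))
    structure(list(params = params, shape = shape, mesh = mesh, az = azs,
                   target_surfaces = targets, mitochondria = mitos,
                   vesicles = vesicles, realized = realized,
                   schema_version = "synmorph-scene/1"),
              class = "syn_scene")
  })
}

#' @export
print.syn_scene <- function(x, ...) {
  r <- x$realized
  cat("<syn_scene> bouton", x$params$bouton_kind, "\n",
      sprintf("  surface %.3f um^2, volume %.3f um^3, %d AZ, %d SVs (%d docked), %d mito\n",
              r$surface_area / UM2, r$volume / UM3, length(x$az),
              sum(r$pool_counts), r$n_docked, length(x$mitochondria)))
  invisible(x)
}

#' Check the geometric invariants of a generated scene
#'
#' Verifies that vesicles lie inside the membrane (5 nm tolerance, docked
#' vesicles may contact it), that no two vesicles overlap by more than the
#' packing tolerance, and that every ground-truth perimeter (recomputed by
#' exhaustive point-to-triangle distance to the assigned patch) falls in its
#' labelled bin.
#'
#' @param scene a `syn_scene`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_scene <- function(scene) {
  v <- scene$vesicles
  if (!nrow(v)) return(invisible(TRUE))
  P <- as.matrix(v[, c("x", "y", "z")])
  ok <- spheres_inside(scene$shape, P, v$radius, tol = 5) | v$docked
  if (!all(ok)) stop("vesicle outside the bouton membrane")
  if (nrow(v) > 1L) {
    dd <- as.matrix(stats::dist(P))
    need <- outer(v$radius, v$radius, "+") - 2.5
    diag(need) <- -Inf
    if (any(dd < need)) stop("vesicle overlap beyond tolerance")
  }
  sv <- v[!v$dense_core, ]
  for (i in seq_len(nrow(sv))) {
    ex <- az_exact_dist(c(sv$x[i], sv$y[i], sv$z[i]), scene$az)
    p <- ex$dist - sv$radius[i]
    if (sv$docked[i] || p < 0) p <- 0
    if (!bin_ok(sv$pool[i], p))
      stop("vesicle ", sv$track_id[i], " perimeter ", round(p, 2),
           " outside labelled bin ", sv$pool[i])
  }
  invisible(TRUE)
}
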
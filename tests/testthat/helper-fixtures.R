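# Shared fixtures: analytic stacks built directly from closed-form shapes so
# reconstruction results can be checked against exact formulas.

# closed circle polygon
circle_poly <- function(r, cx = 0, cy = 0, n = 256L) {
  a <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  xy <- cbind(cx + r * cos(a), cy + r * sin(a))
  rbind(xy, xy[1L, , drop = FALSE])
}

square_poly <- function(side, cx = 0, cy = 0) {
  h <- side / 2
  m <- rbind(c(cx - h, cy - h), c(cx + h, cy - h), c(cx + h, cy + h),
             c(cx - h, cy + h))
  rbind(m, m[1L, , drop = FALSE])
}

# build a minimal syn_stack from a list of per-section polygon sets
make_stack <- function(z_lo, thickness, polys_per_section,
                       marks_per_section = NULL, aligned = TRUE) {
  n <- length(polys_per_section)
  thickness <- rep_len(thickness, n)
  z_l <- z_lo + c(0, cumsum(thickness))[seq_len(n)]
  z_h <- z_l + thickness
  sections <- tibble::tibble(
    index = seq_len(n), z_lo = z_l, z_hi = z_h, z_mid = (z_l + z_h) / 2,
    thickness = thickness, lost = FALSE,
    shift_x = 0, shift_y = 0,
    polygons = polys_per_section,
    marks = if (is.null(marks_per_section)) vector("list", n) else marks_per_section)
  structure(list(sections = sections,
                 alignment_state = if (aligned) "aligned" else "raw",
                 plan = synmorph::section_plan(thickness_nominal = mean(thickness),
                                               thickness_jitter = 0),
                 rng_seed = 0L, schema_version = "synmorph-stack/1"),
            class = "syn_stack")
}

poly_entry <- function(xy, label = "bouton", az = NA_integer_, closed = TRUE) {
  list(label = label, az = az, xy = xy, closed = closed)
}

# sphere sliced into bouton contours at pitch `dz`
sphere_stack <- function(r = 500, dz = 10, n_ring = 256L) {
  z0 <- -r - dz * runif(1)
  bounds <- seq(z0, r + dz, by = dz)
  polys <- list(); keep <- c()
  for (i in seq_len(length(bounds) - 1L)) {
    zm <- (bounds[i] + bounds[i + 1L]) / 2
    if (abs(zm) >= r) { polys[[i]] <- list(); next }
    polys[[i]] <- list(poly_entry(circle_poly(sqrt(r^2 - zm^2), n = n_ring)))
  }
  make_stack(z0, dz, polys)
}

# cylinder of radius r and height h sliced at pitch dz
cylinder_stack <- function(r = 400, h = 1100, dz = 55, n_ring = 256L) {
  nsec <- ceiling(h / dz)
  dz_real <- h / nsec
  polys <- replicate(nsec, list(poly_entry(circle_poly(r, n = n_ring))),
                     simplify = FALSE)
  make_stack(0, dz_real, polys)
}

# small scene parameters that generate quickly in tests
quick_params <- function(rng_seed = 1L, total_sv = 120L, ...) {
  scene_params(bouton_surface_area_target = 3.0e6,
               bouton_volume_target = 0.30e9,
               az_area_targets = 0.15e6,
               total_sv = total_sv,
               pools = pool_spec(frac_p10 = 0.05, frac_p10_20 = 0.05,
                                 frac_20_60 = 0.10, frac_rp = 0.30,
                                 frac_resting = 0.50, docked_fraction = 0.4),
               n_dense_core = 2L, n_mitochondria = 2L,
               mito_volume_fraction_target = 0.10,
               rng_seed = rng_seed, ...)
}

# sphere stack with a polar-cap density annotation: density traces are the
# bouton contour offset `offset` nm inward, present in sections with
# z >= z_cap (the spherical cap). Closed-form cap area: 2*pi*R*(R - z_cap).
cap_stack <- function(r = 500, dz = 10, z_cap = 0, offset = 10) {
  z0 <- -r - dz / 2
  bounds <- seq(z0, r + dz, by = dz)
  polys <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    zm <- (bounds[i] + bounds[i + 1L]) / 2
    if (abs(zm) >= r) { polys[[i]] <- list(); next }
    rr <- sqrt(r^2 - zm^2)
    entry <- list(poly_entry(circle_poly(rr, n = 256L)))
    if (zm >= z_cap && rr > offset) {
      entry[[2L]] <- poly_entry(circle_poly(rr - offset, n = 256L),
                                label = "preaz_density", az = 1L)
    }
    polys[[i]] <- entry
  }
  make_stack(z0, dz, polys)
}

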
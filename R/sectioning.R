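# Observation model 1: serial ultrathin sections (TEM mode).
#
# A Scene is cut into sections of nominal thickness 55 nm (uniform +/- 5 nm
# jitter), each section carrying the planar cross-sections of all labelled
# structures plus vesicle marks, with optional per-section misalignment and
# section loss retained as explicit gaps.

#' Serial-sectioning plan
#'
#' @param thickness_nominal nominal section thickness, nm (default 55).
#' @param thickness_jitter half-width of the uniform thickness jitter, nm
#'   (default 5, i.e. realised thicknesses in 50-60 nm).
#' @param z0 absolute z of the first cutting plane; `NULL` draws a uniform
#'   random offset below the scene so the stack covers it completely.
#' @param loss_probability per-section probability of complete section loss;
#'   lost sections are kept as explicit gaps, never re-indexed away.
#' @param misalignment_sd per-section in-plane translation noise, nm.
#' @param contour_spacing maximum vertex spacing of traced contours, nm.
#' @param density_offset inward offset of the traced density line from the
#'   membrane, nm (annotation convention; default 0 = on the membrane).
#' @return a `section_plan` list.
#' @export
section_plan <- function(thickness_nominal = 55, thickness_jitter = 5,
                         z0 = NULL, loss_probability = 0,
                         misalignment_sd = 0, contour_spacing = 5,
                         density_offset = 0) {
  if (thickness_nominal <= 0) stop("thickness_nominal must be positive")
  if (thickness_jitter < 0 || thickness_jitter >= thickness_nominal)
    stop("thickness_jitter must be nonnegative and below the nominal thickness")
  if (loss_probability < 0 || loss_probability >= 1)
    stop("loss_probability must be in [0, 1)")
  structure(list(thickness_nominal = thickness_nominal,
                 thickness_jitter = thickness_jitter, z0 = z0,
                 loss_probability = loss_probability,
                 misalignment_sd = misalignment_sd,
                 contour_spacing = contour_spacing,
                 density_offset = density_offset), class = "section_plan")
}

# offset a polyline inward (toward the interior of its parent closed contour)
# by a fixed distance, using per-vertex normals
offset_polyline_inward <- function(line, centroid, offset) {
  if (offset == 0 || nrow(line) < 2L) return(line)
  n <- nrow(line)
  d <- diff(line)
  tang <- rbind(d[1L, , drop = FALSE], (d[-nrow(d), , drop = FALSE] + d[-1L, , drop = FALSE]) / 2,
                d[nrow(d), , drop = FALSE])
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
  nrml <- cbind(-tang[, 2L], tang[, 1L])
  toc <- sweep(-line, 2L, -centroid)    # centroid - line
  flip <- rowSums(nrml * toc) < 0
  nrml[flip, ] <- -nrml[flip, , drop = FALSE]
  line + nrml * offset
}

# split a circular membership mask on a closed polygon into contiguous vertex
# runs (each returned as an open polyline)
mask_runs <- function(xy_open, mask) {
  n <- length(mask)
  if (!any(mask)) return(list())
  if (all(mask)) return(list(rbind(xy_open, xy_open[1L, , drop = FALSE])))
  # rotate so position 1 is outside the mask
  start <- which(!mask)[1L]
  ord <- c(start:n, seq_len(start - 1L))
  m <- mask[ord]; xy <- xy_open[ord, , drop = FALSE]
  r <- rle(m)
  ends <- cumsum(r$lengths); begins <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] >= 2L)
      out[[length(out) + 1L]] <- xy[begins[i]:ends[i], , drop = FALSE]
  }
  out
}

# intersect a triangle mesh with the plane z = z0; returns a list of polyline
# chains (k x 2 matrices in the section plane)
slice_mesh_plane <- function(mesh, z0, tol = 1e-6) {
  v <- mesh$vertices; f <- mesh$faces
  zr <- v[, 3L] - z0
  sgn <- zr[f]
  dim(sgn) <- dim(f)
  cross <- (apply(sgn, 1L, max) > 0) & (apply(sgn, 1L, min) < 0)
  if (!any(cross)) return(list())
  segs <- list()
  for (fi in which(cross)) {
    ids <- f[fi, ]
    zz <- zr[ids]
    pts <- list()
    for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
      z1 <- zz[e[1L]]; z2 <- zz[e[2L]]
      if ((z1 > 0) != (z2 > 0)) {
        t <- z1 / (z1 - z2)
        p <- v[ids[e[1L]], 1:2] + t * (v[ids[e[2L]], 1:2] - v[ids[e[1L]], 1:2])
        pts[[length(pts) + 1L]] <- p
      }
    }
    if (length(pts) == 2L) segs[[length(segs) + 1L]] <- rbind(pts[[1L]], pts[[2L]])
  }
  if (!length(segs)) return(list())
  # chain segments into polylines by endpoint matching
  used <- rep(FALSE, length(segs))
  chains <- list()
  match_tol <- 0.5
  ends <- do.call(rbind, lapply(segs, function(s) c(s[1L, ], s[2L, ])))
  while (any(!used)) {
    i <- which(!used)[1L]; used[i] <- TRUE
    chain <- segs[[i]]
    repeat {
      tip <- chain[nrow(chain), ]
      cand <- which(!used)
      if (!length(cand)) break
      d1 <- sqrt((ends[cand, 1L] - tip[1L])^2 + (ends[cand, 2L] - tip[2L])^2)
      d2 <- sqrt((ends[cand, 3L] - tip[1L])^2 + (ends[cand, 4L] - tip[2L])^2)
      j <- which.min(pmin(d1, d2))
      if (min(d1[j], d2[j]) > match_tol) break
      k <- cand[j]; used[k] <- TRUE
      nxt <- if (d1[j] <= d2[j]) segs[[k]][2L, ] else segs[[k]][1L, ]
      chain <- rbind(chain, nxt)
    }
    chains[[length(chains) + 1L]] <- chain
  }
  chains
}

#' Cut a scene into a serial-section contour stack
#'
#' Each retained section holds the planar cross-sections of the bouton,
#' postsynaptic target(s) and mitochondria at the section mid-plane, the
#' presynaptic and postsynaptic density traces of every active zone, and one
#' mark per vesicle whose sphere intersects the section slab (measured
#' diameter = projected profile through the slab). Sections are half-open
#' intervals `[z_lo, z_hi)`; a sphere tangent to a boundary plane belongs to
#' the lower section.
#'
#' @param scene a `syn_scene` from [generate_scene()].
#' @param plan a [section_plan()].
#' @param rng_seed seed for thickness jitter, loss and misalignment draws.
#' @return a `syn_stack` object.
#' @export
section_scene <- function(scene, plan = section_plan(), rng_seed = 1L) {
  stopifnot(inherits(scene, "syn_scene"), inherits(plan, "section_plan"))
  zs <- range(scene$mesh$vertices[, 3L])
  for (tg in scene$target_surfaces)
    zs <- range(c(zs, tg$center[3L] + c(-1, 1) * tg$radius))
  if (diff(zs) <= 0) stop("scene bounding box has zero height")
  with_seed(rng_seed, {
    z0 <- if (is.null(plan$z0)) zs[1L] - runif(1, 0, plan$thickness_nominal) else plan$z0
    bounds <- z0
    while (tail(bounds, 1L) < zs[2L]) {
      t_i <- plan$thickness_nominal +
        if (plan$thickness_jitter > 0) runif(1, -plan$thickness_jitter, plan$thickness_jitter) else 0
      bounds <- c(bounds, tail(bounds, 1L) + t_i)
    }
    n_sec <- length(bounds) - 1L
    lost <- runif(n_sec) < plan$loss_probability
    shifts <- if (plan$misalignment_sd > 0)
      matrix(rnorm(2L * n_sec, 0, plan$misalignment_sd), n_sec, 2L)
    else matrix(0, n_sec, 2L)

    sec_polys <- vector("list", n_sec)
    sec_marks <- vector("list", n_sec)
    v <- scene$vesicles
    for (i in seq_len(n_sec)) {
      if (lost[i]) next
      z_lo <- bounds[i]; z_hi <- bounds[i + 1L]
      z_mid <- (z_lo + z_hi) / 2
      sh <- shifts[i, ]
      polys <- list()
      bout <- shape_cross_section(scene$shape, z_mid, plan$contour_spacing)
      if (!is.null(bout)) {
        open_xy <- bout[-nrow(bout), , drop = FALSE]
        polys[[length(polys) + 1L]] <-
          list(label = "bouton", az = NA_integer_,
               xy = sweep(bout, 2L, -sh), closed = TRUE)
        cen <- polygon_centroid(bout)
        for (az in scene$az) {
          mask <- az_mask(az, cbind(open_xy, z_mid))
          for (run in mask_runs(open_xy, mask)) {
            line <- offset_polyline_inward(run, cen, plan$density_offset)
            polys[[length(polys) + 1L]] <-
              list(label = "preaz_density", az = az$index,
                   xy = sweep(line, 2L, -sh), closed = FALSE)
          }
        }
      }
      for (az in scene$az) {
        for (chain in slice_mesh_plane(az$psd_mesh, z_mid)) {
          polys[[length(polys) + 1L]] <-
            list(label = "psd_density", az = az$index,
                 xy = sweep(chain, 2L, -sh), closed = FALSE)
        }
      }
      for (ti in seq_along(scene$target_surfaces)) {
        tg <- scene$target_surfaces[[ti]]
        dz <- z_mid - tg$center[3L]
        if (abs(dz) < tg$radius) {
          r2 <- sqrt(tg$radius^2 - dz^2)
          ang <- seq(0, 2 * pi, length.out = 97L)
          circ <- cbind(tg$center[1L] + r2 * cos(ang), tg$center[2L] + r2 * sin(ang))
          polys[[length(polys) + 1L]] <-
            list(label = "target", az = ti, xy = sweep(circ, 2L, -sh), closed = TRUE)
        }
      }
      for (mi in seq_along(scene$mitochondria)) {
        m <- scene$mitochondria[[mi]]
        dz <- z_mid - m$center[3L]
        if (abs(dz) < m$semi[3L]) {
          fmt <- sqrt(1 - (dz / m$semi[3L])^2)
          ang <- seq(0, 2 * pi, length.out = 65L)
          ell <- cbind(m$center[1L] + m$semi[1L] * fmt * cos(ang),
                       m$center[2L] + m$semi[2L] * fmt * sin(ang))
          polys[[length(polys) + 1L]] <-
            list(label = "mito", az = mi, xy = sweep(ell, 2L, -sh), closed = TRUE)
        }
      }
      sec_polys[[i]] <- polys
      if (nrow(v)) {
        hit <- (v$z - v$radius < z_hi) & (v$z + v$radius > z_lo)
        if (any(hit)) {
          vv <- v[hit, ]
          centre_slab <- vv$z >= z_lo & vv$z < z_hi
          # a sphere cut by the mid-plane projects a profile that provably
          # lies inside the cell contour; purely tangential profiles (slab
          # overlap without a mid-plane cut) are only annotated when they
          # fall within the cell outline of that image
          crosses_mid <- abs(vv$z - z_mid) < vv$radius
          if (!is.null(bout) && any(!crosses_mid)) {
            inside <- points_in_polygon(cbind(vv$x, vv$y), bout)
            keep_m <- crosses_mid | inside
          } else keep_m <- crosses_mid | is.null(bout)
          vv <- vv[keep_m, , drop = FALSE]
          centre_slab <- centre_slab[keep_m]
          if (nrow(vv)) {
            d_slab <- pmax(pmax(z_lo - vv$z, vv$z - z_hi), 0)
            sec_marks[[i]] <- tibble::tibble(
              track_id = vv$track_id,
              x = vv$x + sh[1L], y = vv$y + sh[2L],
              measured_diameter = 2 * sqrt(pmax(vv$radius^2 - d_slab^2, 1)),
              dense_core = vv$dense_core,
              docked = vv$docked & centre_slab)
          }
        }
      }
    }
    sections <- tibble::tibble(
      index = seq_len(n_sec),
      z_lo = bounds[-(n_sec + 1L)], z_hi = bounds[-1L],
      z_mid = (bounds[-(n_sec + 1L)] + bounds[-1L]) / 2,
      thickness = diff(bounds),
      lost = lost,
      shift_x = shifts[, 1L], shift_y = shifts[, 2L],
      polygons = sec_polys, marks = sec_marks)
    structure(list(sections = sections,
                   alignment_state = if (plan$misalignment_sd > 0) "raw" else "aligned",
                   plan = plan, rng_seed = rng_seed,
                   schema_version = "synmorph-stack/1"),
              class = "syn_stack")
  })
}

#' @export
print.syn_stack <- function(x, ...) {
  s <- x$sections
  cat(sprintf("<syn_stack> %d sections (%d lost), thickness %.1f-%.1f nm, %s\n",
              nrow(s), sum(s$lost), min(s$thickness), max(s$thickness),
              x$alignment_state))
  invisible(x)
}

#' All marks of a stack as one tibble
#'
#' @param stack a `syn_stack`.
#' @return tibble with one row per vesicle mark, carrying `section_index` and
#'   the section mid-plane z.
#' @export
stack_marks <- function(stack) {
  s <- stack$sections
  keep <- !vapply(s$marks, is.null, TRUE)
  if (!any(keep)) {
    return(tibble::tibble(section_index = integer(), z_mid = numeric(),
                          track_id = integer(), x = numeric(), y = numeric(),
                          measured_diameter = numeric(), dense_core = logical(),
                          docked = logical()))
  }
  dplyr::bind_rows(lapply(which(keep), function(i) {
    dplyr::mutate(s$marks[[i]], section_index = s$index[i], z_mid = s$z_mid[i],
                  .before = 1L)
  }))
}
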
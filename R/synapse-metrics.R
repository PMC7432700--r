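# Synapse-level measurements: presynaptic density (PreAZ) extraction by the
# 30 nm apposition rule, PSD area via the contour-length-ratio estimator,
# synaptic cleft widths, and topological AZ shape classification.

density_polys <- function(polys, label) {
  Filter(function(p) identical(p$label, label), polys)
}

#' Extract the presynaptic density area from a bouton model
#'
#' The PreAZ is the subset of the reconstructed bouton membrane lying strictly
#' within `threshold` nm of a traced presynaptic density line. The proximity
#' test is evaluated per section in plane (each lofted mesh triangle is
#' attributed to the section containing its centroid and tested against that
#' section's density traces), then lifted to the mesh: the PreAZ surface area
#' is the summed area of passing triangles.
#'
#' @param model a `syn_bouton_model` from [reconstruct_bouton()].
#' @param threshold apposition distance, nm; inclusion is strict (`< threshold`).
#' @return tibble with one row per active zone: `az`, `sa_preaz_um2`,
#'   `l_preaz_nm` (summed in-plane density trace length), `n_sections`;
#'   the included mesh faces per AZ are attached as attribute `faces`.
#' @export
extract_preaz <- function(model, threshold = 30) {
  stopifnot(inherits(model, "syn_bouton_model"))
  stack <- model$stack
  s <- stack$sections
  az_ids <- sort(unique(unlist(lapply(s$polygons, function(ps) {
    vapply(density_polys(ps, "preaz_density"), function(p) p$az, 0L)
  }))))
  cent <- mesh_face_centroids(model$mesh)
  areas <- mesh_triangle_areas(model$mesh)
  sec_of_face <- findInterval(cent[, 3L], s$z_lo)
  sec_of_face[sec_of_face < 1L | cent[, 3L] >= max(s$z_hi)] <- NA_integer_
  if (!length(az_ids)) {
    warning("no presynaptic density traces in the stack; PreAZ area is 0")
    return(structure(tibble::tibble(az = integer(), sa_preaz_um2 = numeric(),
                                    l_preaz_nm = numeric(), n_sections = integer()),
                     faces = list()))
  }
  out <- vector("list", length(az_ids))
  face_sets <- vector("list", length(az_ids))
  for (k in seq_along(az_ids)) {
    azk <- az_ids[k]
    incl <- logical(nrow(cent))
    l_pre <- 0
    n_sec <- 0L
    for (i in seq_len(nrow(s))) {
      if (s$lost[i]) next
      dens <- Filter(function(p) identical(p$az, azk),
                     density_polys(s$polygons[[i]], "preaz_density"))
      if (!length(dens)) next
      n_sec <- n_sec + 1L
      l_pre <- l_pre + sum(vapply(dens, function(p) polyline_length(p$xy), 0))
      fi <- which(sec_of_face == i)
      if (!length(fi)) next
      dmin <- rep(Inf, length(fi))
      for (p in dens)
        dmin <- pmin(dmin, dist_points_polyline(cent[fi, 1:2, drop = FALSE], p$xy))
      incl[fi[dmin < threshold]] <- TRUE
    }
    face_sets[[k]] <- which(incl)
    out[[k]] <- tibble::tibble(az = azk,
                               sa_preaz_um2 = sum(areas[incl]) / UM2,
                               l_preaz_nm = l_pre, n_sections = n_sec)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "faces") <- face_sets
  res
}

#' Membrane points within the apposition distance of a density trace
#'
#' The elementary strict-inequality predicate behind [extract_preaz()]:
#' a membrane point belongs to the PreAZ iff its in-plane distance to the
#' density trace is strictly less than the threshold.
#'
#' @param points m x 2 membrane points (nm, in-section).
#' @param density density polyline (n x 2).
#' @param threshold nm, default 30.
#' @return logical vector.
#' @export
within_apposition <- function(points, density, threshold = 30) {
  dist_points_polyline(points, density) < threshold
}

#' Estimate the postsynaptic density area from the presynaptic one
#'
#' The contour-length-ratio estimator: `sa_psd = sa_preaz * l_psd / l_preaz`,
#' valid when the two membrane specialisations run parallel across the cleft,
#' so their areas scale as their traced contour lengths.
#'
#' @param sa_preaz PreAZ surface area (any area unit; returned in the same).
#' @param l_psd,l_preaz summed traced contour lengths, nm.
#' @return PSD area estimate.
#' @export
estimate_psd_area <- function(sa_preaz, l_psd, l_preaz) {
  if (any(l_preaz <= 0))
    stop("undefined ratio: l_preaz must be positive")
  sa_preaz * l_psd / l_preaz
}

#' Assemble a cleft-width measurement record
#'
#' @param lateral_1,lateral_2 cleft widths at the two lateral edges, nm.
#' @param central width at the centre, nm.
#' @param perpendicularity_ok was the active zone cut perpendicular to the
#'   section plane? Non-perpendicular profiles are excluded (flagged, with a
#'   message) rather than measured.
#' @param subject_id subject the synapse belongs to.
#' @param az active-zone id.
#' @return one-row tibble with `lateral_mean = (lateral_1 + lateral_2) / 2`
#'   and an `included` flag.
#' @export
measure_cleft <- function(lateral_1, lateral_2, central,
                          perpendicularity_ok = TRUE,
                          subject_id = NA_character_, az = NA_integer_) {
  if (!isTRUE(perpendicularity_ok)) {
    message("cleft profile excluded: active zone not perpendicularly cut")
    return(tibble::tibble(subject_id = subject_id, az = az,
                          lateral_1 = lateral_1, lateral_2 = lateral_2,
                          central = central, lateral_mean = NA_real_,
                          perpendicularity_ok = FALSE, included = FALSE))
  }
  tibble::tibble(subject_id = subject_id, az = az,
                 lateral_1 = lateral_1, lateral_2 = lateral_2,
                 central = central, lateral_mean = (lateral_1 + lateral_2) / 2,
                 perpendicularity_ok = TRUE, included = TRUE)
}

#' Measure cleft widths for every active zone of a stack
#'
#' Follows the standard protocol: in the central section of each AZ (the one
#' with the longest presynaptic density trace), the cleft is measured at the
#' two lateral edges and the centre of the density as the distance to the
#' postsynaptic density trace. Perpendicularity of the cut is assessed from
#' the 3D orientation of the apposition (the unit vector from the PreAZ point
#' cloud to the PSD point cloud must lie close to the section plane).
#'
#' @param stack a `syn_stack` with `preaz_density` and `psd_density` traces.
#' @param subject_id carried into the records.
#' @param max_normal_z maximum |z component| of the apposition direction for a
#'   profile to count as perpendicularly cut.
#' @return tibble of [measure_cleft()] records (one per AZ, excluded profiles
#'   flagged).
#' @export
measure_cleft_stack <- function(stack, subject_id = NA_character_,
                                max_normal_z = 0.35) {
  stopifnot(inherits(stack, "syn_stack"))
  s <- stack$sections
  az_ids <- sort(unique(unlist(lapply(s$polygons, function(ps) {
    vapply(density_polys(ps, "preaz_density"), function(p) p$az, 0L)
  }))))
  out <- list()
  for (azk in az_ids) {
    pre_pts <- list(); psd_pts <- list()
    best_i <- NA_integer_; best_len <- -1
    for (i in seq_len(nrow(s))) {
      if (s$lost[i]) next
      pre <- Filter(function(p) identical(p$az, azk),
                    density_polys(s$polygons[[i]], "preaz_density"))
      psd <- Filter(function(p) identical(p$az, azk),
                    density_polys(s$polygons[[i]], "psd_density"))
      if (length(pre))
        pre_pts[[length(pre_pts) + 1L]] <-
          cbind(do.call(rbind, lapply(pre, `[[`, "xy")), s$z_mid[i])
      if (length(psd))
        psd_pts[[length(psd_pts) + 1L]] <-
          cbind(do.call(rbind, lapply(psd, `[[`, "xy")), s$z_mid[i])
      if (length(pre) && length(psd)) {
        len <- sum(vapply(pre, function(p) polyline_length(p$xy), 0))
        if (len > best_len) { best_len <- len; best_i <- i }
      }
    }
    if (is.na(best_i) || !length(psd_pts)) next
    dir <- colMeans(do.call(rbind, psd_pts)) - colMeans(do.call(rbind, pre_pts))
    dir <- dir / sqrt(sum(dir^2))
    perp <- abs(dir[3L]) <= max_normal_z
    pre <- Filter(function(p) identical(p$az, azk),
                  density_polys(s$polygons[[best_i]], "preaz_density"))
    psd <- Filter(function(p) identical(p$az, azk),
                  density_polys(s$polygons[[best_i]], "psd_density"))
    # use the longest presynaptic run in the central section
    lens <- vapply(pre, function(p) polyline_length(p$xy), 0)
    line <- pre[[which.max(lens)]]$xy
    mid <- line[ceiling(nrow(line) / 2), , drop = FALSE]
    q <- rbind(line[1L, ], line[nrow(line), ], mid)
    dmin <- rep(Inf, 3L)
    for (p in psd) dmin <- pmin(dmin, dist_points_polyline(q, p$xy))
    out[[length(out) + 1L]] <-
      measure_cleft(dmin[1L], dmin[2L], dmin[3L], perpendicularity_ok = perp,
                    subject_id = subject_id, az = azk)
  }
  if (!length(out)) {
    return(tibble::tibble(subject_id = character(), az = integer(),
                          lateral_1 = numeric(), lateral_2 = numeric(),
                          central = numeric(), lateral_mean = numeric(),
                          perpendicularity_ok = logical(), included = logical()))
  }
  dplyr::bind_rows(out)
}

#' Classify the topological shape of an extracted PreAZ patch
#'
#' The patch point cloud is projected onto its best-fitting plane, rasterised,
#' and classified by topology: simply connected patches are `macular` (or
#' `horseshoe` if their boundary concavity — the convex-hull area deficit —
#' exceeds `concavity_threshold`); patches with interior holes are
#' `perforated`, or `ring` when a single hole occupies at least
#' `ring_hole_fraction` of the outline area.
#'
#' @param points n x 3 matrix of points covering the patch (e.g. the vertices
#'   and centroids of the included mesh triangles).
#' @param cell raster cell size, nm.
#' @param concavity_threshold convex-hull area deficit separating horseshoe
#'   from macular (default 0.28; rasterised macular patches sit near 0,
#'   rasterised horseshoes near 0.35-0.45).
#' @param ring_hole_fraction minimum hole/outline area ratio for `ring`.
#' @param min_hole_cells ignore raster holes smaller than this (discretisation
#'   noise).
#' @return one of `"macular"`, `"perforated"`, `"horseshoe"`, `"ring"`.
#' @export
classify_az_shape <- function(points, cell = 16, concavity_threshold = 0.28,
                              ring_hole_fraction = 0.2, min_hole_cells = 3L) {
  if (is.null(points) || !nrow(points)) stop("empty patch")
  if (ncol(points) == 3L) {
    ctr <- colMeans(points)
    pc <- svd(sweep(points, 2L, ctr), nu = 0L, nv = 3L)$v
    pts2 <- sweep(points, 2L, ctr) %*% pc[, 1:2]
  } else pts2 <- points
  gx <- floor(pts2[, 1L] / cell); gy <- floor(pts2[, 2L] / cell)
  gx <- gx - min(gx) + 2L; gy <- gy - min(gy) + 2L
  nr <- max(gx) + 2L; nc <- max(gy) + 2L
  occ <- matrix(FALSE, nr, nc)
  occ[cbind(gx, gy)] <- TRUE
  # flood the complement from the border; unreached complement cells = holes
  outside <- matrix(FALSE, nr, nc)
  queue <- which(!occ & (row(occ) %in% c(1L, nr) | col(occ) %in% c(1L, nc)))
  outside[queue] <- TRUE
  while (length(queue)) {
    cur <- queue
    queue <- integer(0)
    for (d in c(-1L, 1L, -nr, nr)) {
      nb <- cur + d
      ok <- nb >= 1L & nb <= nr * nc
      # prevent row wrap for +/-1 moves
      if (d == -1L) ok <- ok & (cur - 1L) %% nr != 0L
      if (d == 1L) ok <- ok & cur %% nr != 0L
      nb <- nb[ok]
      new <- nb[!outside[nb] & !occ[nb]]
      if (length(new)) { outside[new] <- TRUE; queue <- c(queue, new) }
    }
    queue <- unique(queue)
  }
  hole <- !occ & !outside
  n_occ <- sum(occ)
  # connected hole components of sufficient size
  hole_sizes <- integer(0)
  if (any(hole)) {
    lab <- matrix(0L, nr, nc); nid <- 0L
    for (start in which(hole & TRUE)) {
      if (lab[start] != 0L) next
      nid <- nid + 1L
      q <- start; lab[start] <- nid
      while (length(q)) {
        cur <- q; q <- integer(0)
        for (d in c(-1L, 1L, -nr, nr)) {
          nb <- cur + d
          ok <- nb >= 1L & nb <= nr * nc
          if (d == -1L) ok <- ok & (cur - 1L) %% nr != 0L
          if (d == 1L) ok <- ok & cur %% nr != 0L
          nb <- nb[ok]
          new <- nb[hole[nb] & lab[nb] == 0L]
          if (length(new)) { lab[new] <- nid; q <- c(q, new) }
        }
        q <- unique(q)
      }
    }
    hole_sizes <- tabulate(lab[lab > 0L])
    hole_sizes <- hole_sizes[hole_sizes >= min_hole_cells]
  }
  if (length(hole_sizes)) {
    frac <- sum(hole_sizes) / (n_occ + sum(hole_sizes))
    if (length(hole_sizes) == 1L && frac >= ring_hole_fraction) return("ring")
    return("perforated")
  }
  ctr2 <- cbind((gx - 0.5) * 1, (gy - 0.5) * 1)
  cells <- unique(cbind(gx, gy))
  h <- grDevices::chull(cells)
  hull <- cells[h, , drop = FALSE]
  hull_area <- polygon_area(rbind(hull, hull[1L, , drop = FALSE]))
  deficit <- 1 - n_occ / max(hull_area, 1)
  if (deficit > concavity_threshold) "horseshoe" else "macular"
}
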
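# 3D reconstruction from contour stacks: linear (translation) alignment,
# Cavalieri volumes, and lofted surface models.

section_label_polys <- function(polys, label) {
  Filter(function(p) identical(p$label, label), polys)
}

#' Align a contour stack by consecutive-section translation
#'
#' Estimates one in-plane translation per section so that the centroids of
#' matched bouton contours coincide between consecutive retained sections
#' (the linear-transformation alignment used in serial-section workflows,
#' restricted to translation). Idempotent on already-aligned stacks.
#'
#' @param stack a `syn_stack`.
#' @return the aligned stack (`alignment_state == "aligned"`); the applied
#'   per-section corrections are stored in `attr(, "applied_translations")`.
#' @export
align_stack <- function(stack) {
  stopifnot(inherits(stack, "syn_stack"))
  s <- stack$sections
  if (nrow(s) < 2L) stop("alignment needs at least 2 sections")
  present <- which(!s$lost & vapply(s$polygons, function(p) {
    length(section_label_polys(p, "bouton")) > 0
  }, TRUE))
  if (length(present) < 2L) stop("fewer than 2 sections with bouton contours")
  cents <- lapply(present, function(i) {
    bp <- section_label_polys(s$polygons[[i]], "bouton")
    do.call(rbind, lapply(bp, function(p) polygon_centroid(p$xy)))
  })
  trans <- matrix(0, nrow(s), 2L)
  acc <- c(0, 0)
  for (k in seq_along(present)[-1L]) {
    i_prev <- present[k - 1L]; i <- present[k]
    c_prev <- cents[[k - 1L]]; c_cur <- cents[[k]]
    # nearest-centroid matching with a 500 nm gate on the raw contours;
    # aligned positions satisfy c_i + T_i = c_{i-1} + T_{i-1}, so the
    # correction accumulates the negated raw centroid displacement
    dmat <- outer(c_cur[, 1L], c_prev[, 1L], "-")^2 +
      outer(c_cur[, 2L], c_prev[, 2L], "-")^2
    j <- apply(dmat, 1L, which.min)
    ok <- sqrt(dmat[cbind(seq_len(nrow(dmat)), j)]) < 500
    if (!any(ok))
      stop("no matchable bouton contours between sections ", s$index[i_prev],
           " and ", s$index[i])
    disp <- colMeans(c_cur[ok, , drop = FALSE] - c_prev[j[ok], , drop = FALSE])
    acc <- acc - disp
    trans[i, ] <- acc
    if (k < length(present)) {
      nxt <- present[k + 1L]
      if (nxt - i > 1L) trans[(i + 1L):(nxt - 1L), ] <- rep(acc, each = nxt - i - 1L)
    }
  }
  # fill sections before the first present one
  if (present[1L] > 1L) trans[seq_len(present[1L] - 1L), ] <- 0
  if (max(present) < nrow(s))
    trans[(max(present) + 1L):nrow(s), ] <- rep(acc, each = nrow(s) - max(present))
  out <- stack
  for (i in seq_len(nrow(s))) {
    if (all(trans[i, ] == 0)) next
    out$sections$polygons[[i]] <- lapply(s$polygons[[i]], function(p) {
      p$xy <- sweep(p$xy, 2L, -trans[i, ]); p
    })
    if (!is.null(s$marks[[i]])) {
      out$sections$marks[[i]]$x <- s$marks[[i]]$x + trans[i, 1L]
      out$sections$marks[[i]]$y <- s$marks[[i]]$y + trans[i, 2L]
    }
  }
  out$alignment_state <- "aligned"
  attr(out, "applied_translations") <- trans
  out
}

# group contours of one label across sections into objects by
# centroid-proximity chaining (500 nm gate); returns a tibble
# (section row, poly index within section, object id)
group_contours <- function(stack, label, gate = 500) {
  s <- stack$sections
  rows <- list()
  for (i in seq_len(nrow(s))) {
    if (s$lost[i]) next
    ps <- s$polygons[[i]]
    for (k in seq_along(ps)) {
      if (!identical(ps[[k]]$label, label)) next
      cen <- polygon_centroid(ps[[k]]$xy)
      rows[[length(rows) + 1L]] <- data.frame(
        sec = i, poly = k, cx = cen[1L], cy = cen[2L],
        area = polygon_area(ps[[k]]$xy))
    }
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  df$object <- NA_integer_
  next_id <- 1L
  open <- data.frame(object = integer(), cx = numeric(), cy = numeric(),
                     sec = integer())
  for (i in sort(unique(df$sec))) {
    cur <- which(df$sec == i)
    taken <- integer(0)
    for (r in cur) {
      if (nrow(open)) {
        d <- sqrt((open$cx - df$cx[r])^2 + (open$cy - df$cy[r])^2)
        d[open$object %in% taken] <- Inf
        jm <- which.min(d)
        if (length(jm) && is.finite(d[jm]) && d[jm] < gate) {
          df$object[r] <- open$object[jm]
          taken <- c(taken, open$object[jm])
          open$cx[jm] <- df$cx[r]; open$cy[jm] <- df$cy[r]; open$sec[jm] <- i
          next
        }
      }
      df$object[r] <- next_id
      open <- rbind(open, data.frame(object = next_id, cx = df$cx[r],
                                     cy = df$cy[r], sec = i))
      taken <- c(taken, next_id)
      next_id <- next_id + 1L
    }
    open <- open[i - open$sec <= 3L, , drop = FALSE]
  }
  df
}

#' Cavalieri volume of a labelled object in a contour stack
#'
#' The classical section-based estimator: the sum over sections of contour
#' area times the section's realised thickness. Lost sections contribute
#' nothing (gaps are flagged, never interpolated).
#'
#' @param stack a `syn_stack` (aligned or alignment-free).
#' @param label contour label (default `"bouton"`).
#' @return volume in um^3 (summed over objects of that label).
#' @export
cavalieri_volume <- function(stack, label = "bouton") {
  stopifnot(inherits(stack, "syn_stack"))
  s <- stack$sections
  total <- 0
  for (i in seq_len(nrow(s))) {
    if (s$lost[i]) next
    for (p in section_label_polys(s$polygons[[i]], label)) {
      if (!is_closed_polygon(p$xy))
        stop("unclosed polygon for label '", label, "' in section ", s$index[i])
      total <- total + polygon_area(p$xy) * s$thickness[i]
    }
  }
  total / UM3
}

# loft a single ordered sequence of closed contours into a triangle strip
# mesh; contours: list of closed polygons; zs: their plane heights
loft_rings <- function(contours, zs, n_ring = 192L, cap = c(TRUE, TRUE)) {
  m <- length(contours)
  rings <- vector("list", m)
  for (i in seq_len(m)) {
    xy <- resample_closed(ensure_ccw(contours[[i]]), n_ring)[-(n_ring + 1L), , drop = FALSE]
    rings[[i]] <- xy
  }
  # align ring starting vertices to the previous ring (minimise summed offset)
  for (i in seq_len(m)[-1L]) {
    prev <- rings[[i - 1L]]; cur <- rings[[i]]
    best <- 0L; bestd <- Inf
    for (off in 0:(n_ring - 1L)) {
      idx <- ((seq_len(n_ring) - 1L + off) %% n_ring) + 1L
      d <- sum((cur[idx, 1L] - prev[, 1L])^2 + (cur[idx, 2L] - prev[, 2L])^2)
      if (d < bestd) { bestd <- d; best <- off }
    }
    idx <- ((seq_len(n_ring) - 1L + best) %% n_ring) + 1L
    rings[[i]] <- cur[idx, , drop = FALSE]
  }
  verts <- do.call(rbind, lapply(seq_len(m), function(i) cbind(rings[[i]], zs[i])))
  faces <- list()
  for (i in seq_len(m - 1L)) {
    a <- (i - 1L) * n_ring + seq_len(n_ring)
    b <- a + n_ring
    a2 <- c(a[-1L], a[1L]); b2 <- c(b[-1L], b[1L])
    # shortest-diagonal split of each quad
    d1 <- rowSums((verts[a, , drop = FALSE] - verts[b2, , drop = FALSE])^2)
    d2 <- rowSums((verts[a2, , drop = FALSE] - verts[b, , drop = FALSE])^2)
    use1 <- d1 <= d2
    # consistent outward winding for counter-clockwise rings
    faces[[length(faces) + 1L]] <- rbind(
      cbind(a[use1], a2[use1], b2[use1]), cbind(a[use1], b2[use1], b[use1]),
      cbind(a[!use1], a2[!use1], b[!use1]), cbind(a2[!use1], b2[!use1], b[!use1]))
  }
  nv <- nrow(verts)
  if (cap[1L]) {
    cen <- colMeans(verts[seq_len(n_ring), , drop = FALSE])
    verts <- rbind(verts, cen)
    j <- seq_len(n_ring); j2 <- c(j[-1L], j[1L])
    faces[[length(faces) + 1L]] <- cbind(nrow(verts), j2, j)
  }
  if (cap[2L]) {
    base <- (m - 1L) * n_ring
    cen <- colMeans(verts[base + seq_len(n_ring), , drop = FALSE])
    verts <- rbind(verts, cen)
    j <- base + seq_len(n_ring); j2 <- c(j[-1L], j[1L])
    faces[[length(faces) + 1L]] <- cbind(nrow(verts), j, j2)
  }
  new_mesh(verts, do.call(rbind, faces))
}

#' Loft a labelled object into a closed surface model
#'
#' Consecutive contours are resampled to a common vertex count, rotationally
#' registered, and stitched with shortest-diagonal triangulation; first and
#' last contours are capped. A gap of lost sections wider than `max_gap`
#' sections marks the model truncated (the gap is not bridged).
#'
#' @param stack a `syn_stack`.
#' @param label contour label.
#' @param object object id from contour grouping (default 1, the largest use
#'   case being the single bouton).
#' @param max_gap widest bridgeable run of lost sections.
#' @return list with `mesh`, `surface_area` (um^2), `mesh_volume` (um^3),
#'   `completeness` (`"complete"`/`"truncated"`) and the per-section band
#'   assignment used for area attribution.
#' @export
loft_surface <- function(stack, label = "bouton", object = 1L, max_gap = 2L) {
  stopifnot(inherits(stack, "syn_stack"))
  grp <- group_contours(stack, label)
  if (is.null(grp)) stop("no contours with label '", label, "'")
  grp <- grp[grp$object == object, , drop = FALSE]
  if (!nrow(grp)) stop("no object ", object, " for label '", label, "'")
  if (any(table(grp$sec) > 1L))
    stop("branching contours for one object are not loftable; ",
         "check contour grouping")
  s <- stack$sections
  secs <- sort(grp$sec)
  truncated <- FALSE
  if (length(secs) > 1L && max(diff(secs)) > max_gap + 1L) truncated <- TRUE
  # each section holds exactly one contour of this object; take it directly
  contours <- lapply(seq_along(secs), function(k) {
    i <- secs[k]
    pk <- grp$poly[grp$sec == i]
    s$polygons[[i]][[pk]]$xy
  })
  zs <- s$z_mid[secs]
  mesh <- loft_rings(contours, zs)
  band <- data.frame(section = secs, z_mid = zs)
  list(mesh = mesh,
       surface_area = mesh_area(mesh) / UM2,
       mesh_volume = mesh_volume(mesh) / UM3,
       completeness = if (truncated) "truncated" else "complete",
       sections = band)
}

#' Reconstruct a bouton model from a contour stack
#'
#' Aligns the stack if needed, then computes the Cavalieri volume, the lofted
#' surface model and per-label volumes for mitochondria.
#'
#' @param stack a `syn_stack`.
#' @return a `syn_bouton_model` with `volume` (um^3, Cavalieri),
#'   `surface_area` (um^2, lofted), `mesh`, `mito_volume` (um^3),
#'   `mito_volume_fraction`, `n_mitochondria`, `completeness` and the aligned
#'   stack.
#' @export
reconstruct_bouton <- function(stack) {
  stopifnot(inherits(stack, "syn_stack"))
  if (!identical(stack$alignment_state, "aligned")) stack <- align_stack(stack)
  loft <- loft_surface(stack, "bouton")
  vol <- cavalieri_volume(stack, "bouton")
  mito_vol <- cavalieri_volume(stack, "mito")
  # organelles are annotated as distinct objects (colour codes); count ids
  mito_ids <- unlist(lapply(stack$sections$polygons, function(ps) {
    vapply(Filter(function(p) identical(p$label, "mito"), ps),
           function(p) p$az, 0L)
  }))
  n_mito <- length(unique(mito_ids))
  # completeness per the serial-section rule: the bouton must close (taper
  # out) within the series on both ends
  areas <- vapply(seq_len(nrow(stack$sections)), function(i) {
    bp <- section_label_polys(stack$sections$polygons[[i]], "bouton")
    if (!length(bp)) return(NA_real_)
    sum(vapply(bp, function(p) polygon_area(p$xy), 0))
  }, 0)
  nz <- which(!is.na(areas))
  # the first and last observed profiles must be small relative to the
  # bouton waist; with ~55 nm sections the outermost observable profile of a
  # complete bouton can still reach ~a third of the waist area
  closes <- length(nz) >= 3L &&
    areas[nz[1L]] < 0.4 * max(areas, na.rm = TRUE) &&
    areas[nz[length(nz)]] < 0.4 * max(areas, na.rm = TRUE)
  completeness <- if (loft$completeness == "truncated" || !closes)
    "truncated" else "complete"
  structure(list(stack = stack, mesh = loft$mesh,
                 volume = vol, surface_area = loft$surface_area,
                 mesh_volume = loft$mesh_volume,
                 mito_volume = mito_vol,
                 mito_volume_fraction = if (vol > 0) mito_vol / vol else NA_real_,
                 n_mitochondria = n_mito,
                 completeness = completeness),
            class = "syn_bouton_model")
}

#' @export
print.syn_bouton_model <- function(x, ...) {
  cat(sprintf("<syn_bouton_model> %s; volume %.3f um^3 (Cavalieri), surface %.3f um^2, %d mitochondria (%.1f%% of volume)\n",
              x$completeness, x$volume, x$surface_area, x$n_mitochondria,
              100 * x$mito_volume_fraction))
  invisible(x)
}
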
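# Vesicle perimeter analysis and pool classification.
#
# The perimeter p of a vesicle is the minimal distance between its centre of
# gravity and the presynaptic density of an active zone, diminished by one
# vesicle radius — the gap the vesicle must bridge to touch the membrane
# specialisation. Pools: p <= 10 (strict RRP), p <= 20 (loose RRP,
# cumulative), 20-60 (intermediate), 60-200 (recycling), > 200 nm (resting).

#' Compute vesicle perimeters against the presynaptic density traces
#'
#' For every vesicle mark, the centre distance is the minimal 2D distance to
#' any presynaptic density trace in the same section (the per-section
#' protocol); `perimeter_p = center_distance - measured_diameter / 2`,
#' negative values clamped to zero (a vesicle overlapping the density is
#' touching it). Marks in sections without any density trace cannot be
#' measured in plane; by default they fall back to the cross-section distance
#' (minimum over all sections of `sqrt(inplane^2 + dz^2)`), flagged
#' `"3d_fallback"`. `method = "3d"` uses the cross-section distance for all
#' marks.
#'
#' @param stack a `syn_stack`.
#' @param method `"2d"` (per-section, with cross-section fallback) or `"3d"`.
#' @param marks optionally a pre-filtered mark tibble (e.g. from
#'   [primary_marks()]); default all marks of the stack.
#' @return tibble of vesicle records: section, position, measured diameter,
#'   `center_distance`, `perimeter_p`, assigned `az`, `method_used`, flags.
#' @export
vesicle_perimeter <- function(stack, method = c("2d", "3d"), marks = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "syn_stack"))
  if (is.null(marks)) marks <- stack_marks(stack)
  s <- stack$sections
  dens <- list()  # per section: list of xy matrices + az
  for (i in seq_len(nrow(s))) {
    if (s$lost[i]) next
    dd <- Filter(function(p) identical(p$label, "preaz_density"), s$polygons[[i]])
    if (length(dd))
      dens[[as.character(i)]] <- list(
        z = s$z_mid[i], half_t = s$thickness[i] / 2,
        lines = lapply(dd, `[[`, "xy"),
        az = vapply(dd, function(p) p$az, 0L))
  }
  if (!length(dens))
    stop("no presynaptic density traces anywhere in the stack; ",
         "perimeters are undefined")
  n <- nrow(marks)
  cd <- rep(NA_real_, n); azv <- rep(NA_integer_, n)
  used <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- c(marks$x[i], marks$y[i])
    key <- as.character(marks$section_index[i])
    if (method == "2d" && !is.null(dens[[key]])) {
      dl <- dens[[key]]
      best <- Inf; barg <- NA_integer_
      for (k in seq_along(dl$lines)) {
        d <- dist_points_polyline(matrix(p, 1L), dl$lines[[k]])
        if (d < best) { best <- d; barg <- dl$az[k] }
      }
      cd[i] <- best; azv[i] <- barg; used[i] <- "2d"
    } else {
      best <- Inf; barg <- NA_integer_
      for (sec in dens) {
        # a trace samples the density surface throughout its slab, so the
        # axial offset is credited the slab half-thickness
        dz <- max(abs(sec$z - marks$z_mid[i]) - sec$half_t, 0)
        for (k in seq_along(sec$lines)) {
          d2 <- dist_points_polyline(matrix(p, 1L), sec$lines[[k]])
          d <- sqrt(d2^2 + dz^2)
          if (d < best) { best <- d; barg <- sec$az[k] }
        }
      }
      cd[i] <- best; azv[i] <- barg
      used[i] <- if (method == "3d") "3d" else "3d_fallback"
    }
  }
  out <- marks
  out$center_distance <- cd
  out$perimeter_p <- pmax(cd - marks$measured_diameter / 2, 0)
  out$az <- azv
  out$method_used <- used
  out
}

#' Classify vesicle records into perimeter pools
#'
#' Bin edges (nm): `p <= 10` strict RRP; `10 < p <= 20` completing the loose
#' RRP criterion (`n_p20` is cumulative); `20 < p < 60` intermediate;
#' `60 <= p <= 200` recycling; `p > 200` resting. Dense-core vesicles and
#' records with undefined perimeters are excluded (and counted as excluded).
#'
#' @param records tibble from [vesicle_perimeter()] (needs `perimeter_p`;
#'   `docked`/`dense_core` flags are honoured when present).
#' @param edges numeric bin edges, default `c(10, 20, 60, 200)`.
#' @return one-row tibble of pool counts with the per-record pool assignment
#'   attached as attribute `"records"`.
#' @export
classify_pools <- function(records, edges = c(10, 20, 60, 200)) {
  stopifnot(length(edges) == 4L, !is.unsorted(edges))
  p <- records$perimeter_p
  dense <- if ("dense_core" %in% names(records)) records$dense_core else
    rep(FALSE, length(p))
  excl <- is.na(p) | !is.finite(p) | dense
  pv <- p[!excl]
  pool <- cut(pv, breaks = c(-Inf, edges, Inf), right = TRUE,
              labels = c("RRP_p10", "RRP_p10_20", "intermediate_20_60",
                         "RP_60_200", "resting_gt200"))
  # the recycling bin is closed on both sides ([60, 200]) while the
  # intermediate bin is open; cut() above puts 60 into the intermediate bin,
  # so move exact-60 records across
  at60 <- !is.na(pv) & pv == edges[3L]
  pool[at60] <- "RP_60_200"
  recs <- records[!excl, , drop = FALSE]
  recs$pool <- as.character(pool)
  docked <- if ("docked" %in% names(recs)) sum(recs$docked) else 0L
  counts <- table(pool)
  out <- tibble::tibble(
    n_total = length(pv),
    n_p10 = as.integer(counts[["RRP_p10"]]),
    n_p20 = as.integer(counts[["RRP_p10"]] + counts[["RRP_p10_20"]]),
    n_intermediate = as.integer(counts[["intermediate_20_60"]]),
    n_rp = as.integer(counts[["RP_60_200"]]),
    n_resting = as.integer(counts[["resting_gt200"]]),
    n_docked = as.integer(docked),
    n_excluded = sum(excl))
  attr(out, "records") <- recs
  out
}

#' Count docked vesicles
#'
#' Docked vesicles (membrane-contacting, p = 0, or already fused) are a
#' subset of the strict p10 readily releasable pool.
#'
#' @param records a vesicle-record tibble with a `docked` flag.
#' @return integer count.
#' @export
count_docked <- function(records) {
  if (!"docked" %in% names(records)) return(0L)
  dense <- if ("dense_core" %in% names(records)) records$dense_core else FALSE
  sum(records$docked & !dense, na.rm = TRUE)
}

#' De-duplicate dense-core vesicle marks across adjacent sections
#'
#' A large dense-core vesicle appears in several consecutive sections; double
#' counts are removed by keeping, per object, only the mark in the section
#' where its measured diameter is largest (ties: the lower section). Marks
#' are grouped into objects when they lie in sections at most
#' `max_section_gap` apart and their in-plane centres fall within a quarter
#' of their summed diameters. Small clear vesicles receive no such
#' correction; only marks flagged `dense_core` are touched when the flag is
#' present.
#'
#' @param marks mark tibble (needs `section_index`, `x`, `y`,
#'   `measured_diameter`).
#' @param max_section_gap adjacency span in section indices (default 1).
#' @return the de-duplicated mark tibble (one row per distinct object).
#' @export
dedup_dense_core <- function(marks, max_section_gap = 1L) {
  if (!nrow(marks)) return(marks)
  sub <- if ("dense_core" %in% names(marks)) marks[marks$dense_core, , drop = FALSE] else marks
  rest <- if ("dense_core" %in% names(marks)) marks[!marks$dense_core, , drop = FALSE] else
    marks[0L, , drop = FALSE]
  n <- nrow(sub)
  if (n <= 1L) return(dplyr::bind_rows(rest, sub))
  edges <- list()
  for (i in seq_len(n - 1L)) {
    dz <- abs(sub$section_index[(i + 1L):n] - sub$section_index[i])
    dd <- sqrt((sub$x[(i + 1L):n] - sub$x[i])^2 + (sub$y[(i + 1L):n] - sub$y[i])^2)
    thr <- (sub$measured_diameter[(i + 1L):n] + sub$measured_diameter[i]) / 4
    hit <- which(dz <= max_section_gap & dd < thr)
    if (length(hit)) edges[[length(edges) + 1L]] <- cbind(i, i + hit)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  keep <- vapply(split(seq_len(n), comp), function(ix) {
    best <- ix[order(-sub$measured_diameter[ix], sub$section_index[ix])]
    best[1L]
  }, 0L)
  dplyr::bind_rows(rest, sub[sort(keep), , drop = FALSE])
}
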
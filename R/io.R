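# Serialisation: package-defined JSON schemas for scenes and contour stacks,
# and ASCII PLY export for meshes.

params_to_list <- function(params) {
  p <- unclass(params)
  p$pools <- unclass(p$pools)
  p$cleft <- unclass(p$cleft)
  p
}

params_from_list <- function(lst) {
  lst$pools <- do.call(pool_spec, lst$pools)
  lst$cleft <- do.call(cleft_spec, lst$cleft)
  do.call(scene_params, lst)
}

#' Write a scene to the package's JSON schema
#'
#' Scenes are deterministic functions of their parameters (including the
#' seed), so the schema stores the parameters, the realised quantities and
#' the ground-truth vesicle table; [read_scene_json()] regenerates the full
#' geometry from the parameters and checks the realised quantities match.
#'
#' @param scene a `syn_scene`.
#' @param path output file ("scene.json").
#' @return `path`, invisibly.
#' @export
write_scene_json <- function(scene, path) {
  stopifnot(inherits(scene, "syn_scene"))
  obj <- list(schema_version = scene$schema_version,
              params = params_to_list(scene$params),
              realized = scene$realized,
              vesicles = scene$vesicles)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a scene from the package's JSON schema
#'
#' @param path a file written by [write_scene_json()].
#' @param check verify that the regenerated realised quantities match the
#'   stored ones.
#' @return a `syn_scene`.
#' @export
read_scene_json <- function(path, check = TRUE) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema_version, "synmorph-scene/1"))
    stop("unsupported scene schema: ", obj$schema_version)
  scene <- generate_scene(params_from_list(obj$params))
  if (check) {
    stopifnot(abs(scene$realized$surface_area - obj$realized$surface_area) <
                1e-6 * obj$realized$surface_area)
    stopifnot(nrow(scene$vesicles) == nrow(obj$vesicles))
  }
  scene
}

#' Write a contour stack to the package's JSON schema
#'
#' Full-fidelity serialisation of the stack: per-section z interval,
#' thickness, loss flag, labelled polygons/polylines (vertex lists) and
#' vesicle marks.
#'
#' @param stack a `syn_stack`.
#' @param path output file ("stack.json").
#' @return `path`, invisibly.
#' @export
write_stack_json <- function(stack, path) {
  stopifnot(inherits(stack, "syn_stack"))
  s <- stack$sections
  secs <- lapply(seq_len(nrow(s)), function(i) {
    list(index = s$index[i], z_lo = s$z_lo[i], z_hi = s$z_hi[i],
         thickness = s$thickness[i], lost = s$lost[i],
         polygons = lapply(s$polygons[[i]], function(p) {
           list(label = p$label, az = p$az, closed = p$closed,
                x = p$xy[, 1L], y = p$xy[, 2L])
         }),
         marks = if (is.null(s$marks[[i]])) NULL else s$marks[[i]])
  })
  obj <- list(schema_version = stack$schema_version,
              alignment_state = stack$alignment_state,
              plan = unclass(stack$plan), rng_seed = stack$rng_seed,
              sections = secs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a contour stack from the package's JSON schema
#' @param path a file written by [write_stack_json()].
#' @return a `syn_stack`.
#' @export
read_stack_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema_version, "synmorph-stack/1"))
    stop("unsupported stack schema: ", obj$schema_version)
  n <- length(obj$sections)
  polys <- vector("list", n); marks <- vector("list", n)
  meta <- matrix(0, n, 4L)
  lost <- logical(n)
  for (i in seq_len(n)) {
    sec <- obj$sections[[i]]
    meta[i, ] <- c(sec$index, sec$z_lo, sec$z_hi, sec$thickness)
    lost[i] <- isTRUE(sec$lost)
    polys[[i]] <- lapply(sec$polygons, function(p) {
      list(label = p$label,
           az = {
             ai <- suppressWarnings(as.integer(p$az))
             if (length(ai) != 1L || is.na(ai)) NA_integer_ else ai
           },
           xy = cbind(unlist(p$x), unlist(p$y)), closed = isTRUE(p$closed))
    })
    if (!is.null(sec$marks) && length(sec$marks)) {
      rows <- lapply(sec$marks, function(r) {
        tibble::tibble(track_id = as.integer(r$track_id),
                       x = as.numeric(r$x), y = as.numeric(r$y),
                       measured_diameter = as.numeric(r$measured_diameter),
                       dense_core = isTRUE(r$dense_core),
                       docked = isTRUE(r$docked))
      })
      marks[[i]] <- dplyr::bind_rows(rows)
    }
  }
  sections <- tibble::tibble(
    index = as.integer(meta[, 1L]), z_lo = meta[, 2L], z_hi = meta[, 3L],
    z_mid = (meta[, 2L] + meta[, 3L]) / 2, thickness = meta[, 4L],
    lost = lost,
    shift_x = rep(0, n), shift_y = rep(0, n),
    polygons = polys, marks = marks)
  plan <- obj$plan
  plan$z0 <- if (is.null(plan$z0)) NULL else as.numeric(plan$z0)
  structure(list(sections = sections,
                 alignment_state = obj$alignment_state,
                 plan = do.call(section_plan, plan),
                 rng_seed = obj$rng_seed,
                 schema_version = obj$schema_version),
            class = "syn_stack")
}

#' Export a triangle mesh as ASCII PLY
#'
#' @param mesh list with `vertices` (n x 3, nm) and `faces` (m x 3, 1-based).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.3f %.3f %.3f", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1L] - 1L,
                     mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
  invisible(path)
}
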
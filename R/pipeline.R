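# End-to-end study pipeline: scene generation -> sectioning -> reconstruction
# -> synapse metrics -> vesicle pools -> study table -> statistics -> reports.

#' Keep one mark per vesicle (the annotator's convention)
#'
#' Sectioning emits a mark in every section a vesicle intersects; a human
#' annotator marks each vesicle once, in the image where its profile is
#' largest. This selects, per vesicle track, the mark of maximal measured
#' diameter (ties: lower section).
#'
#' @param marks tibble from [stack_marks()].
#' @return filtered mark tibble.
#' @export
primary_marks <- function(marks) {
  if (!nrow(marks)) return(marks)
  marks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(dplyr::desc(.data$measured_diameter), .data$section_index,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$section_index, .data$track_id)
}

#' Pipeline configuration
#'
#' @param layers character vector of presets to simulate (`"L4_TLN"`,
#'   `"L5_TLN"`).
#' @param n_boutons boutons per subject and layer.
#' @param n_subjects subjects per layer.
#' @param modality `"tem"`, `"fibsem"` or both.
#' @param seed integer master seed; every downstream draw derives from it.
#' @param vary_targets draw per-bouton targets from the preset's
#'   between-bouton spread (`TRUE`, for realistic study tables) or use the
#'   preset means exactly (`FALSE`).
#' @param plan a [section_plan()].
#' @param out_dir directory for report files (`NULL` = no files written).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(layers = "L5_TLN", n_boutons = 2L, n_subjects = 2L,
                            modality = "tem", seed = 1L, vary_targets = TRUE,
                            plan = section_plan(), out_dir = NULL) {
  stopifnot(all(layers %in% names(.tln_presets)),
            all(modality %in% c("tem", "fibsem")))
  structure(list(layers = layers, n_boutons = as.integer(n_boutons),
                 n_subjects = as.integer(n_subjects), modality = modality,
                 seed = as.integer(seed), vary_targets = isTRUE(vary_targets),
                 plan = plan, out_dir = out_dir), class = "pipeline_config")
}

derive_seed <- function(seed, ...) {
  ix <- c(...)
  as.integer((as.double(seed) * 10007 + sum(ix * (101 + seq_along(ix)))) %% 2147483647)
}

# per-bouton parameter draw around the preset means, using the preset's
# between-bouton SDs (truncated to plausible ranges)
draw_bouton_params <- function(layer, rng_seed, vary = TRUE) {
  base <- scene_preset(layer, rng_seed = rng_seed)
  if (!vary) return(base)
  means <- attr(base, "layer_means")
  with_seed(derive_seed(rng_seed, 7L), {
    s_fac <- exp(rnorm(1, 0, 0.5 * means$sd$surface / means$surface))
    surface <- means$surface * s_fac
    volume <- means$volume * s_fac^1.5 * exp(rnorm(1, 0, 0.08))
    az <- max(0.04 * UM2, rnorm(1, means$preaz, 0.5 * means$sd$preaz))
    n_az <- sample(means$n_az_range, 1L,
                   prob = rev(seq_along(means$n_az_range))^2)
    total <- round(min(5000, max(150,
                                 rnorm(1, means$total_sv, 0.3 * means$sd$total_sv))))
    base$bouton_surface_area_target <- surface
    base$bouton_volume_target <- volume
    base$n_az <- n_az
    base$az_area_targets <- rep(az / n_az^0.5, n_az)
    base$az_shape <- rep("macular", n_az)
    base$total_sv <- as.integer(total)
    base
  })
}

measure_bouton <- function(scene, plan, rng_seed, modality = "tem") {
  stack <- section_scene(scene, plan, rng_seed = rng_seed)
  model <- reconstruct_bouton(stack)
  pre <- extract_preaz(model)
  dens_len <- az_density_lengths(stack)[, c("az", "l_psd_nm")]
  pre2 <- dplyr::left_join(pre, dens_len, by = "az")
  pre2$sa_psd_um2 <- ifelse(pre2$l_preaz_nm > 0,
                            estimate_psd_area(pre2$sa_preaz_um2,
                                              pre2$l_psd_nm, pre2$l_preaz_nm),
                            NA_real_)
  faces <- attr(pre, "faces")
  shapes <- vapply(seq_len(nrow(pre)), function(k) {
    fi <- faces[[k]]
    if (!length(fi)) return(NA_character_)
    f <- model$mesh$faces[fi, , drop = FALSE]
    pts <- rbind(model$mesh$vertices[f[, 1L], ], model$mesh$vertices[f[, 2L], ],
                 model$mesh$vertices[f[, 3L], ], mesh_face_centroids(model$mesh)[fi, ])
    classify_az_shape(pts)
  }, "")
  cleft <- measure_cleft_stack(stack)
  # one record per vesicle: measure perimeters on the primary (largest-
  # profile) marks only, per the annotation convention
  recs <- vesicle_perimeter(stack, marks = primary_marks(stack_marks(stack)))
  pools <- classify_pools(recs)
  dc <- dedup_dense_core(stack_marks(stack))
  n_dense <- sum(dc$dense_core)
  out <- list(stack = stack, model = model, preaz = pre2, az_shapes = shapes,
              cleft = cleft, records = recs, pools = pools,
              n_dense_core = n_dense)
  if ("fibsem" %in% modality) {
    vol <- voxelize_scene(scene, spacing = c(5, 5, 50))
    out$n_detect_fibsem <- nrow(detect_vesicles_voxel(vol))
  }
  out
}

#' Summed density trace lengths per active zone
#'
#' @param stack a `syn_stack`.
#' @return tibble: `az`, `l_preaz_nm`, `l_psd_nm`.
#' @export
az_density_lengths <- function(stack) {
  s <- stack$sections
  rows <- list()
  for (i in seq_len(nrow(s))) {
    if (s$lost[i]) next
    for (p in s$polygons[[i]]) {
      if (p$label %in% c("preaz_density", "psd_density"))
        rows[[length(rows) + 1L]] <- data.frame(az = p$az, label = p$label,
                                                len = polyline_length(p$xy))
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(az = integer(), l_preaz_nm = numeric(),
                          l_psd_nm = numeric()))
  }
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(len ~ az + label, df, sum)
  wide <- tidyr::pivot_wider(tibble::as_tibble(agg), names_from = "label",
                             values_from = "len", values_fill = 0)
  tibble::tibble(az = as.integer(wide$az),
                 l_preaz_nm = if ("preaz_density" %in% names(wide))
                   wide$preaz_density else 0,
                 l_psd_nm = if ("psd_density" %in% names(wide))
                   wide$psd_density else 0)
}

#' Run the full morphometry pipeline
#'
#' Executes scene generation, sectioning, reconstruction, synapse metrics,
#' vesicle-pool classification and statistics for every configured subject,
#' layer and bouton, and (optionally) writes the study-table CSV, a
#' provenance JSON and a run log. Fully deterministic for a fixed
#' configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @return a `syn_study` list: `study_table` (one row per bouton),
#'   `aggregates` (per-layer two-level subject aggregation of each
#'   parameter), `stats` (Kruskal-Wallis + post-hoc U across layers, when
#'   more than one layer is configured), `files`, `log`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  logf <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(config$out_dir))
        unlink(file.path(config$out_dir,
                         c("study_table.csv", "provenance.json", "run_log.txt")))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  rows <- list()
  logf("run_pipeline seed=%d layers=%s boutons=%d subjects=%d modality=%s",
       config$seed, paste(config$layers, collapse = "+"), config$n_boutons,
       config$n_subjects, paste(config$modality, collapse = "+"))
  for (li in seq_along(config$layers)) {
    layer <- config$layers[li]
    for (si in seq_len(config$n_subjects)) {
      subject <- sprintf("%s_subj%02d", sub("_TLN", "", layer), si)
      for (bi in seq_len(config$n_boutons)) {
        sd_i <- derive_seed(config$seed, li, si, bi)
        params <- stage("scene_params",
                        draw_bouton_params(layer, sd_i, config$vary_targets))
        scene <- stage("generate_scene", generate_scene(params))
        meas <- stage("measure", measure_bouton(scene, config$plan,
                                                derive_seed(sd_i, 13L),
                                                config$modality))
        cl_in <- meas$cleft[meas$cleft$included, , drop = FALSE]
        logf("%s bouton %d: %d sections, %d AZ, %d/%d cleft profiles kept, %d SV records (%d excluded)",
             subject, bi, nrow(meas$stack$sections), nrow(meas$preaz),
             nrow(cl_in), nrow(meas$cleft), meas$pools$n_total,
             meas$pools$n_excluded)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = subject, layer = layer, bouton_id = bi,
          completeness = meas$model$completeness,
          surface_area_um2 = meas$model$surface_area,
          volume_um3 = meas$model$volume,
          n_az = nrow(meas$preaz),
          preaz_area_um2 = mean(meas$preaz$sa_preaz_um2),
          psd_area_um2 = mean(meas$preaz$sa_psd_um2),
          az_shape = meas$az_shapes[1L],
          cleft_lateral_nm = if (nrow(cl_in)) mean(cl_in$lateral_mean) else NA_real_,
          cleft_central_nm = if (nrow(cl_in)) mean(cl_in$central) else NA_real_,
          n_sv_total = meas$pools$n_total,
          n_p10 = meas$pools$n_p10, n_p20 = meas$pools$n_p20,
          n_intermediate = meas$pools$n_intermediate,
          n_rp = meas$pools$n_rp, n_resting = meas$pools$n_resting,
          n_docked = meas$pools$n_docked,
          n_dense_core = meas$n_dense_core,
          n_mitochondria = meas$model$n_mitochondria,
          mito_volume_fraction = meas$model$mito_volume_fraction,
          n_detect_fibsem = if (is.null(meas$n_detect_fibsem)) NA_integer_ else
            meas$n_detect_fibsem)
      }
    }
  }
  study <- dplyr::bind_rows(rows)
  params_num <- c("surface_area_um2", "volume_um3", "preaz_area_um2",
                  "psd_area_um2", "cleft_lateral_nm", "cleft_central_nm",
                  "n_sv_total", "n_p10", "n_p20", "n_rp", "n_resting")
  aggregates <- stage("aggregate", {
    res <- list()
    for (layer in config$layers) {
      sub <- study[study$layer == layer, , drop = FALSE]
      res[[layer]] <- lapply(stats::setNames(params_num, params_num), function(pn) {
        tryCatch(suppressWarnings(aggregate_subjects(sub, !!rlang::sym(pn))),
                 error = function(e) NULL)
      })
    }
    res
  })
  stats_res <- NULL
  if (length(config$layers) > 1L) {
    stats_res <- stage("stats", {
      lapply(stats::setNames(params_num, params_num), function(pn) {
        v <- study[[pn]]
        ok <- !is.na(v)
        if (min(table(study$layer[ok])) < 2L) return(NULL)
        kruskal_posthoc(study[ok, , drop = FALSE], !!rlang::sym(pn), layer)
      })
    })
  }
  files <- list()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files$study_table <- file.path(config$out_dir, "study_table.csv")
    study <- stage("report", write_study_csv(study, files$study_table))
    files$provenance <- file.path(config$out_dir, "provenance.json")
    prov <- list(package = "synmorph",
                 version = as.character(utils::packageVersion("synmorph")),
                 config = list(layers = config$layers,
                               n_boutons = config$n_boutons,
                               n_subjects = config$n_subjects,
                               modality = config$modality, seed = config$seed,
                               vary_targets = config$vary_targets,
                               plan = unclass(config$plan)))
    jsonlite::write_json(prov, files$provenance, auto_unbox = TRUE,
                         digits = NA, null = "null")
    files$log <- file.path(config$out_dir, "run_log.txt")
    writeLines(log_lines, files$log)
  }
  structure(list(study_table = study, aggregates = aggregates,
                 stats = stats_res, files = files, log = log_lines,
                 config = config), class = "syn_study")
}

#' @export
print.syn_study <- function(x, ...) {
  cat(sprintf("<syn_study> %d boutons, layers %s\n", nrow(x$study_table),
              paste(x$config$layers, collapse = ", ")))
  print(x$study_table, n = 6)
  invisible(x)
}

#' Write a study table with the fixed decimal formatting policy
#'
#' Numeric columns are written with six decimal places, so a written table
#' re-read with [read_study_csv()] reproduces every value bit for bit. The
#' canonicalised (rounded) table is returned invisibly.
#'
#' @param study study-table tibble.
#' @param path output CSV.
#' @return the canonicalised tibble, invisibly.
#' @export
write_study_csv <- function(study, path) {
  fmt6 <- function(x) {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x)
    out[ok] <- as.numeric(sprintf("%.6f", x[ok]))
    out
  }
  canon <- study
  for (cn in names(canon)) {
    if (is.double(canon[[cn]])) canon[[cn]] <- fmt6(canon[[cn]])
  }
  out <- canon
  for (cn in names(out)) {
    if (is.double(out[[cn]])) {
      chr <- sprintf("%.6f", out[[cn]])
      chr[is.na(out[[cn]])] <- NA_character_
      out[[cn]] <- chr
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(canon)
}

#' Read a study table CSV
#' @param path file written by [write_study_csv()].
#' @return tibble.
#' @export
read_study_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  # all-missing numeric columns come back logical; restore the numeric type
  for (cn in names(df)) {
    if (is.logical(df[[cn]]) && all(is.na(df[[cn]]))) df[[cn]] <- as.numeric(df[[cn]])
  }
  tibble::as_tibble(df)
}
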
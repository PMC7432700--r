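# Study-level statistics: two-level subject aggregation and the
# Kruskal-Wallis / post-hoc Mann-Whitney workflow standard in quantitative
# synaptic morphometry.

#' Two-level subject aggregation of a morphometric parameter
#'
#' Within-subject means are computed first, then an unweighted mean and SD
#' across subjects (each subject contributes equally regardless of how many
#' synapses it provided). With a single subject the grand SD is undefined and
#' reported as `NA`.
#'
#' @param data a data frame / tibble (e.g. a study table).
#' @param parameter column to aggregate (tidy-eval).
#' @param subject grouping column identifying subjects (default `subject_id`).
#' @return a `syn_aggregate` list: `per_subject` tibble (subject, n, mean,
#'   sd) and `overall` one-row tibble (grand mean, SD over subject means,
#'   n_subjects, n_observations). Subjects with no non-missing values are
#'   excluded with a warning.
#' @export
aggregate_subjects <- function(data, parameter, subject = subject_id) {
  par_q <- rlang::enquo(parameter)
  sub_q <- rlang::enquo(subject)
  per <- data |>
    dplyr::group_by(!!sub_q) |>
    dplyr::summarise(n = sum(!is.na(!!par_q)),
                     mean = mean(!!par_q, na.rm = TRUE),
                     sd = stats::sd(!!par_q, na.rm = TRUE), .groups = "drop")
  empty <- per$n == 0L
  if (any(empty)) {
    warning(sum(empty), " subject(s) with no observations excluded")
    per <- per[!empty, , drop = FALSE]
  }
  if (!nrow(per)) stop("no subjects with observations")
  overall <- tibble::tibble(
    mean = mean(per$mean),
    sd = if (nrow(per) > 1L) stats::sd(per$mean) else NA_real_,
    n_subjects = nrow(per),
    n_observations = sum(per$n))
  structure(list(per_subject = per, overall = overall,
                 parameter = rlang::as_label(par_q)),
            class = "syn_aggregate")
}

#' @export
print.syn_aggregate <- function(x, ...) {
  cat(sprintf("<syn_aggregate> %s: grand mean %.4g +/- %.4g SD over %d subjects (%d observations)\n",
              x$parameter, x$overall$mean, x$overall$sd, x$overall$n_subjects,
              x$overall$n_observations))
  invisible(x)
}

#' @export
tidy.syn_aggregate <- function(x, ...) x$per_subject

#' @export
glance.syn_aggregate <- function(x, ...) x$overall

#' Kruskal-Wallis test with post-hoc pairwise Mann-Whitney U tests
#'
#' The omnibus H statistic (tie-corrected, from [stats::kruskal.test()])
#' followed by two-sided Mann-Whitney U tests for every group pair, with
#' Bonferroni multiplicity adjustment by default.
#'
#' @param data data frame with a value column and a group column, or a named
#'   list of numeric vectors.
#' @param value,group tidy-eval columns when `data` is a data frame.
#' @param p_adjust_method passed to [stats::p.adjust()] (default
#'   `"bonferroni"`).
#' @return a `syn_kruskal` object with the omnibus result, per-group
#'   summaries and the pairwise table; see `tidy()` and `glance()` methods.
#' @export
kruskal_posthoc <- function(data, value = NULL, group = NULL,
                            p_adjust_method = "bonferroni") {
  if (is.data.frame(data)) {
    val_q <- rlang::enquo(value); grp_q <- rlang::enquo(group)
    v <- rlang::eval_tidy(val_q, data)
    g <- as.character(rlang::eval_tidy(grp_q, data))
    groups <- split(v, g)
  } else {
    groups <- data
    if (is.null(names(groups)))
      names(groups) <- paste0("group", seq_along(groups))
  }
  groups <- lapply(groups, function(x) x[!is.na(x)])
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- vapply(groups, length, 0L)
  if (any(sizes < 2L))
    stop("group '", names(groups)[which(sizes < 2L)[1L]],
         "' has fewer than 2 values")
  kw <- stats::kruskal.test(unname(groups))
  pairs <- utils::combn(names(groups), 2L)
  pw <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    wt <- suppressWarnings(stats::wilcox.test(groups[[a]], groups[[b]],
                                              alternative = "two.sided",
                                              exact = FALSE, correct = TRUE))
    tibble::tibble(group1 = a, group2 = b, U = unname(wt$statistic),
                   p_value = wt$p.value)
  })
  pw <- dplyr::bind_rows(pw)
  pw$p_adjusted <- stats::p.adjust(pw$p_value, method = p_adjust_method)
  gs <- tibble::tibble(
    group = names(groups), n = sizes,
    mean = vapply(groups, mean, 0), sd = vapply(groups, stats::sd, 0))
  structure(list(H = unname(kw$statistic), df = unname(kw$parameter),
                 p_value = kw$p.value, pairwise = pw, group_stats = gs,
                 p_adjust_method = p_adjust_method),
            class = "syn_kruskal")
}

#' @export
print.syn_kruskal <- function(x, ...) {
  cat(sprintf("<syn_kruskal> H = %.4g, df = %d, p = %.4g (%d groups); post-hoc U (%s):\n",
              x$H, x$df, x$p_value, nrow(x$group_stats), x$p_adjust_method))
  print(as.data.frame(x$pairwise), row.names = FALSE)
  invisible(x)
}

#' @rdname kruskal_posthoc
#' @param x a `syn_kruskal` object.
#' @param ... unused.
#' @export
tidy.syn_kruskal <- function(x, ...) x$pairwise

#' @rdname kruskal_posthoc
#' @export
glance.syn_kruskal <- function(x, ...) {
  tibble::tibble(H = x$H, df = x$df, p_value = x$p_value,
                 n_groups = nrow(x$group_stats),
                 n = sum(x$group_stats$n))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
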
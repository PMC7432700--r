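# ggplot2 figures for stacks, vesicle records and study tables.

#' Plot one section of a contour stack
#'
#' Draws the labelled contours and vesicle marks of a single section, the way
#' an annotated EM image looks.
#'
#' @param stack a `syn_stack`.
#' @param index section index (default: the section with the largest bouton
#'   contour).
#' @return a ggplot object.
#' @export
plot_section <- function(stack, index = NULL) {
  s <- stack$sections
  if (is.null(index)) {
    areas <- vapply(seq_len(nrow(s)), function(i) {
      bp <- section_label_polys(s$polygons[[i]], "bouton")
      if (!length(bp)) return(0)
      max(vapply(bp, function(p) polygon_area(p$xy), 0))
    }, 0)
    index <- which.max(areas)
  }
  ps <- s$polygons[[match(index, s$index)]]
  dfs <- lapply(seq_along(ps), function(k) {
    p <- ps[[k]]
    tibble::tibble(x = p$xy[, 1L] / 1000, y = p$xy[, 2L] / 1000,
                   label = p$label, id = k)
  })
  df <- dplyr::bind_rows(dfs)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        group = .data$id,
                                        colour = .data$label)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("section %d (z = %.0f nm)", index,
                                  s$z_mid[match(index, s$index)]))
  mk <- s$marks[[match(index, s$index)]]
  if (!is.null(mk) && nrow(mk)) {
    g <- g + ggplot2::geom_point(
      data = tibble::tibble(x = mk$x / 1000, y = mk$y / 1000,
                            size = mk$measured_diameter),
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$size),
      inherit.aes = FALSE, shape = 1, alpha = 0.6) +
      ggplot2::scale_size_continuous(range = c(0.5, 3), guide = "none")
  }
  g + ggplot2::theme_minimal()
}

#' Histogram of vesicle perimeters with the pool bin edges
#'
#' @param records tibble from [vesicle_perimeter()].
#' @param binwidth histogram bin width, nm.
#' @return a ggplot object.
#' @export
plot_perimeter_hist <- function(records, binwidth = 20) {
  df <- records[!is.na(records$perimeter_p), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$perimeter_p)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(10, 20, 60, 200), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "perimeter p (nm)", y = "vesicles",
                  title = "vesicle perimeter distribution (pool edges dashed)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplots of the main morphometric parameters by layer
#'
#' @param object a `syn_study` from [run_pipeline()].
#' @param parameters columns of the study table to show.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.syn_study <- function(object,
                               parameters = c("surface_area_um2", "volume_um3",
                                              "preaz_area_um2", "n_sv_total"),
                               ...) {
  long <- tidyr::pivot_longer(object$study_table,
                              cols = dplyr::all_of(parameters),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$layer, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_section
#' @param object a `syn_stack`.
#' @param ... passed to [plot_section()].
#' @export
autoplot.syn_stack <- function(object, ...) plot_section(object, ...)

#' @importFrom rlang .data
NULL
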
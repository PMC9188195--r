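#' Raster display of a plane or mask
#'
#' @param x a [plane2d()] or a matrix.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot plane2d
#' @export
autoplot.plane2d <- function(x, ...) {
  m <- as_plane_matrix(x)
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity")
}

#' Volcano plot of differential results
#'
#' @param diff a [classify_differential()] table.
#' @return a ggplot object.
#' @export
plot_volcano <- function(diff) {
  ggplot2::ggplot(diff, ggplot2::aes(.data$log2fc,
                                     -log10(.data$p_value),
                                     colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = "significant")
}

#' Running-sum plot of an enrichment result
#'
#' @param enr a [running_sum_enrichment()] result.
#' @return a ggplot object.
#' @export
plot_running_sum <- function(enr) {
  df <- tibble(rank = seq_along(enr$running), running = enr$running)
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$running)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_rug(data = tibble(rank = enr$positions),
                      ggplot2::aes(x = .data$rank), inherit.aes = FALSE,
                      sides = "b") +
    ggplot2::labs(y = "running enrichment", title = enr$set)
}

#' Bar chart of per-structure plaque densities
#'
#' @param summaries a [structure_summary()] (or rolled-up) table.
#' @param corrected use the z-sampling-corrected density.
#' @return a ggplot object.
#' @export
plot_structure_density <- function(summaries, corrected = FALSE) {
  y <- if (corrected) "plaques_per_mm3_corrected" else "plaques_per_mm3"
  ggplot2::ggplot(summaries,
                  ggplot2::aes(stats::reorder(.data$structure_name,
                                              .data[[y]]),
                               .data[[y]])) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "plaques / mm^3")
}
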
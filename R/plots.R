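#' Plot a hydropathy profile with predicted TM segments
#'
#' @param profile Output of [hydropathy_profile()].
#' @param segments Optional output of [predict_tm_segments()]; shaded when
#'   given.
#' @param threshold Cutoff drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_hydropathy <- function(profile, segments = NULL, threshold = 1.6) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$position, y = .data$hydropathy)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Residue", y = "Mean Kyte-Doolittle hydropathy") +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments) > 0) {
    p <- p + ggplot2::geom_rect(
      data = segments,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15)
  }
  p
}

#' Heatmap of a (normalized) expression matrix
#'
#' Rows ordered by hierarchical clustering leaf order.
#'
#' @param matrix An `fpkm_matrix` (normalized or raw).
#' @param clustering Optional result of [hierarchical_cluster()]; computed
#'   when missing.
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(matrix, clustering = NULL) {
  if (is.null(clustering)) clustering <- hierarchical_cluster(matrix)
  long <- tidyr::pivot_longer(as_tibble(matrix), -"gene_id",
                              names_to = "sample", values_to = "value")
  long$gene_id <- factor(long$gene_id, levels = rev(clustering$order))
  long$sample <- factor(long$sample,
                        levels = setdiff(names(matrix), "gene_id"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$gene_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "navy", high = "firebrick",
                                 name = "log2(FPKM+1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Line plot of salt-stress time courses
#'
#' @param profiles Long profile tibble (`gene_id`, `timepoint`, `treated`,
#'   optionally `control`).
#' @return A ggplot object, faceted per gene.
#' @export
plot_salt_response <- function(profiles) {
  long <- tidyr::pivot_longer(
    profiles, dplyr::any_of(c("treated", "control")),
    names_to = "series", values_to = "fpkm")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint, y = .data$fpkm,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~gene_id, scales = "free_y") +
    ggplot2::labs(x = "Hours after treatment", y = "FPKM",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
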
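# ggplot2 views of the main result types

#' Plot the gene-overlap partition of panel designs
#'
#' Bar chart of the Venn-cell sizes from [compare_gene_sets()], ordered by
#' the number of panels sharing each cell.
#'
#' @param designs List of [panel_design()] objects.
#' @return A ggplot.
#' @export
plot_gene_overlap <- function(designs) {
  partition <- compare_gene_sets(designs)
  partition |>
    mutate(cell = factor(.data$cell, levels = .data$cell),
           n_panels = lengths(.data$panels)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$cell, y = .data$n_genes,
                                 fill = factor(.data$n_panels))) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_genes), vjust = -0.3,
                       size = 3) +
    ggplot2::labs(x = "panels sharing the genes", y = "genes",
                  fill = "panels") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Heatmap of mean depth by gene and panel
#'
#' @param summaries List of gene-granularity `coverage_summary` objects.
#' @return A ggplot.
#' @export
plot_coverage_heatmap <- function(summaries) {
  long <- bind_rows(map(summaries, function(s) {
    tibble(panel = attr(s, "panel") %||% "panel", gene = s$gene,
           mean_depth = s$mean_depth)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$panel, y = .data$gene,
                                     fill = .data$mean_depth)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#fff7bc", high = "#99000d") +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean depth") +
    ggplot2::theme_minimal()
}

#' Tile view of a four-state call matrix
#'
#' One tile per variant x panel, colored by call status.
#'
#' @param matrix A `call_matrix`.
#' @return A ggplot.
#' @export
plot_call_matrix <- function(matrix) {
  long <- status_long(matrix) |>
    mutate(row = paste(.data$sample, .data$gene, sep = " / "))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$panel, y = .data$row,
                                     fill = .data$status)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(C = "#2c7fb8", NC = "#d95f02",
                                          NI = "#bdbdbd", ND = "#f0f0f0")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "status") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatterplot of paired VAFs between two panels
#'
#' @param object A [vaf_concordance()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vaf_concordance <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$vaf_a, y = .data$vaf_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = paste("VAF,", object$panels[1]), y = paste("VAF,", object$panels[2]),
      title = sprintf("r^2 = %s over %d shared calls",
                      ifelse(is.na(object$r_squared), "undefined",
                             sprintf("%.3f", object$r_squared)),
                      object$n_pairs)) +
    ggplot2::theme_minimal()
}
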
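# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a WCSS elbow curve
#'
#' @param elbow Result of [elbow_select_k()].
#' @return A ggplot: WCSS against k with the selected elbow marked.
#' @export
plot_elbow <- function(elbow) {
  ggplot2::ggplot(elbow$curve, ggplot2::aes(x = .data$k, y = .data$wcss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = elbow$k, linetype = "dashed") +
    ggplot2::labs(x = "number of nodes (k)",
                  y = "within-cluster sum of squares",
                  title = sprintf("Elbow selection: k = %d", elbow$k)) +
    ggplot2::theme_minimal()
}

#' Scaled-median phenotype heatmap
#'
#' @param phenotypes A `node_phenotype` tibble.
#' @return A ggplot tile heatmap (nodes x markers, scaled medians).
#' @export
plot_phenotype_heatmap <- function(phenotypes) {
  ggplot2::ggplot(phenotypes,
                  ggplot2::aes(x = .data$marker, y = .data$node_id,
                               fill = .data$scaled_median)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "scaled\nmedian") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Box-and-whisker plot of node frequencies by group
#'
#' @param freq Long frequency tibble ([frequency_matrix()]).
#' @param nodes Node ids to show (e.g. the significant ones).
#' @param group_var Grouping column (default `"cohort"`).
#' @return A ggplot with one panel per node.
#' @export
plot_node_frequencies <- function(freq, nodes, group_var = "cohort") {
  sub <- filter(freq, .data$node_id %in% nodes,
                !is.na(.data[[group_var]]))
  ggplot2::ggplot(sub, ggplot2::aes(x = .data[[group_var]], y = .data$freq,
                                    fill = .data[[group_var]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~node_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "node frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Autoplot a signed network
#'
#' Force-directed layout (seeded, deterministic); node color by lineage,
#' edge color by correlation sign.
#'
#' @param object A `signed_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.signed_network <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nd <- mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  pos <- setNames(seq_len(nrow(nd)), nd$node_id)
  ed <- mutate(object$edges,
               x = nd$x[pos[.data$from]], y = nd$y[pos[.data$from]],
               xend = nd$x[pos[.data$to]], yend = nd$y[pos[.data$to]])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       color = .data$sign),
                          linewidth = 0.3, alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(positive = "#d73027",
                                           negative = "#1a9850")) +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$lineage),
                        shape = 21, size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "edge sign", fill = "lineage")
}
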
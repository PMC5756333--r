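#' Plot per-sample QC statistics
#'
#' One panel per statistic (total counts, detected features, dropout rate,
#' and size factor when present), samples on the x axis.
#'
#' @param qc Tibble from [sample_qc_stats()].
#' @return A ggplot object.
#' @export
plot_qc <- function(qc) {
  long <- tidyr::pivot_longer(qc, -"sample_id", names_to = "statistic",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "sample", y = NULL, title = "Sample QC statistics") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Rank-frequency plot (log-log)
#'
#' @param rf Tibble from [rank_frequency()].
#' @return A ggplot object.
#' @export
plot_rank_frequency <- function(rf) {
  ggplot2::ggplot(rf, ggplot2::aes(x = .data$rank, y = .data$frequency)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "frequency", title = "Rank-frequency") +
    ggplot2::theme_bw()
}

#' Mean-variability plot
#'
#' Per-feature standard deviation against mean on log scales.
#'
#' @param mv Tibble from [mean_variability()].
#' @return A ggplot object.
#' @export
plot_mean_variability <- function(mv) {
  ggplot2::ggplot(mv, ggplot2::aes(x = .data$mean, y = .data$sd)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean", y = "standard deviation",
                  title = "Mean-variability") +
    ggplot2::theme_bw()
}

#' Volcano plot of a DE result
#'
#' @param object A `de_result`.
#' @param alpha Significance threshold to highlight (default 0.05).
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.de_result <- function(object, alpha = 0.05, ...) {
  tab <- tidy(object)
  tab$significant <- tab$p_adjusted <= alpha
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log2_fc,
                                    y = -log10(pmax(.data$p_value, 1e-300)),
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = paste0("Mann-Whitney DE: ", object$group_a, " vs ",
                                 object$group_b)) +
    ggplot2::theme_bw()
}

#' Bar plot of top TF influence scores
#'
#' @param object A `tf_influence_table`.
#' @param top_n Number of TFs to show (default 20).
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tf_influence_table <- function(object, top_n = 20, ...) {
  tab <- utils::head(dplyr::arrange(tibble::as_tibble(object), .data$rank), top_n)
  tab$tf <- factor(tab$tf, levels = rev(tab$tf))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$influence_score, y = .data$tf)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = paste0("influence score (", attr(object, "option"), ")"),
                  y = NULL, title = "Candidate trans-differentiation factors") +
    ggplot2::theme_bw()
}

#' Plot the data map derivation graph
#'
#' Tree-style layout of the derivation DAG, labelling nodes with their label
#' and dimensions and highlighting the active node.
#'
#' @param map A `data_map`.
#' @return A ggplot object.
#' @export
plot_data_map <- function(map) {
  g <- map_igraph(map)
  coords <- igraph::layout_as_tree(g, root = map$root_id)
  nodes <- tibble::tibble(
    node_id = igraph::V(g)$name,
    x = coords[, 1], y = coords[, 2],
    label = vapply(igraph::V(g)$name,
                   function(id) map$nodes[[id]]$label, character(1)),
    active = igraph::V(g)$name == map$active_id)
  edges <- dplyr::bind_rows(lapply(map$edges, function(e) {
    tibble::tibble(
      x = nodes$x[nodes$node_id == e$parent],
      y = nodes$y[nodes$node_id == e$parent],
      xend = nodes$x[nodes$node_id == e$child],
      yend = nodes$y[nodes$node_id == e$child],
      op = e$op$op_name)
  }))
  p <- ggplot2::ggplot()
  if (nrow(edges)) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey50")
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$active), size = 5) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(title = "Data map") +
    ggplot2::theme_void()
}
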
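#' Volcano plot of a differential screen
#'
#' @param records [diff_expression()] output.
#' @param p_cut,fdr_cut Cutoffs used to color significant genes.
#' @return A ggplot.
#' @export
plot_volcano <- function(records, p_cut = 0.05, fdr_cut = 0.05) {
  dat <- volcano_coordinates(records) |>
    dplyr::left_join(dplyr::select(records, "gene_id", "p_value", "fdr",
                                   "trend"),
                     by = "gene_id") |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$p_value < p_cut & .data$fdr < fdr_cut & .data$trend == "up" ~ "up",
        .data$p_value < p_cut & .data$fdr < fdr_cut & .data$trend == "down" ~ "down",
        TRUE ~ "not significant"
      ))
  ggplot2::ggplot(dat, ggplot2::aes(.data$log2_fold_change,
                                    .data$neg_log10_p,
                                    color = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_color_manual(values = c(up = "#d73027",
                                           down = "#4575b4",
                                           `not significant` = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", color = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of top enriched terms
#'
#' @param records [enrich()] output.
#' @param direction Which direction family to show.
#' @param top_n Terms shown (by p-value).
#' @return A ggplot.
#' @export
plot_enrichment <- function(records, direction = "both", top_n = 15L) {
  dat <- records |>
    dplyr::filter(.data$direction == !!direction, .data$significant) |>
    dplyr::slice_min(.data$p_value, n = top_n, with_ties = FALSE) |>
    dplyr::mutate(name = stats::reorder(.data$name, .data$R_e))
  ggplot2::ggplot(dat, ggplot2::aes(.data$R_e, .data$name,
                                    fill = -log10(.data$p_value))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "enrichment ratio Re", y = NULL,
                  fill = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Plot a gene network
#'
#' Fruchterman-Reingold layout; node size scales with degree, color with
#' regulation (red up, blue down, yellow both), solid edges positive and
#' dashed negative — the usual rendering of signal / co-expression figures.
#'
#' @param object A `gene_network`.
#' @param label_top Label the `label_top` highest-degree nodes.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gene_network
#' @export
autoplot.gene_network <- function(object, label_top = 10L, ...) {
  g <- object$graph
  set.seed(1L)  # layout reproducibility only
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes |>
    dplyr::mutate(x = xy[match(.data$node, igraph::V(g)$name), 1],
                  y = xy[match(.data$node, igraph::V(g)$name), 2],
                  regulation = if ("regulation" %in% names(object$nodes))
                    dplyr::coalesce(.data$regulation, "both") else "both")
  edges <- object$edges |>
    dplyr::mutate(x = nodes$x[match(.data$from, nodes$node)],
                  y = nodes$y[match(.data$from, nodes$node)],
                  xend = nodes$x[match(.data$to, nodes$node)],
                  yend = nodes$y[match(.data$to, nodes$node)])
  lab <- nodes |> dplyr::slice_max(.data$degree, n = label_top,
                                   with_ties = FALSE)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$sign),
      color = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, size = .data$degree,
                   color = .data$regulation)) +
    ggplot2::geom_text(
      data = lab,
      ggplot2::aes(.data$x, .data$y, label = .data$node),
      size = 2.5, vjust = -1) +
    ggplot2::scale_color_manual(values = c(up = "#d73027",
                                           down = "#4575b4",
                                           both = "#fee090"),
                                na.value = "grey50") +
    ggplot2::scale_linetype_manual(values = c(`+` = "solid",
                                              `-` = "dashed")) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "degree", color = NULL, linetype = "sign")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
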
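#' Build the directed signal network over differential genes
#'
#' Restricts a curated gene-gene interaction edge list to edges whose
#' endpoints are both differential; the surviving directed graph carries
#' each gene's regulation trend plus degree, in/outdegree and betweenness.
#'
#' @param differential Tibble with `gene_id` and `trend` (the selected
#'   differential genes).
#' @param interaction_edges Tibble with `from`, `to` and optionally `sign`.
#' @return A directed `gene_network`. An empty surviving edge set yields an
#'   empty network with a warning (not an error).
#' @export
build_signal_network <- function(differential, interaction_edges) {
  interaction_edges <- tibble::as_tibble(interaction_edges)
  de <- unique(differential$gene_id)
  if (nrow(interaction_edges)) {
    keep <- interaction_edges$from %in% de & interaction_edges$to %in% de
    dropped <- sum(!keep)
    if (dropped > 0) {
      inform(sprintf(
        "build_signal_network: dropped %d edge(s) with a non-differential endpoint.",
        dropped))
    }
    interaction_edges <- interaction_edges[keep, ]
  }
  if (nrow(interaction_edges) == 0L) {
    warn("signal network has no surviving edges.")
    return(gene_network(tibble::tibble(from = character(), to = character()),
                        directed = TRUE))
  }
  nodes <- differential |>
    dplyr::filter(.data$gene_id %in%
                    c(interaction_edges$from, interaction_edges$to)) |>
    dplyr::distinct(.data$gene_id, .data$trend) |>
    dplyr::rename(node = "gene_id", regulation = "trend")
  gene_network(interaction_edges, nodes = nodes, directed = TRUE)
}

#' Rank signal-network genes by betweenness centrality
#'
#' @param network Signal network from [build_signal_network()].
#' @return Tibble (`gene_id`, `betweenness`, `degree`, `indegree`,
#'   `outdegree`, `trend`) sorted by descending betweenness, then degree,
#'   then gene id — the hub table shape.
#' @export
rank_hub_genes <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  network$nodes |>
    dplyr::transmute(
      gene_id = .data$node,
      betweenness = .data$betweenness,
      degree = .data$degree,
      indegree = .data$indegree,
      outdegree = .data$outdegree,
      trend = if ("regulation" %in% names(network$nodes))
        .data$regulation else NA_character_
    ) |>
    dplyr::arrange(dplyr::desc(.data$betweenness), dplyr::desc(.data$degree),
                   .data$gene_id)
}
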
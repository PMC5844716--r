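#' Build an attributed gene/term network
#'
#' The common graph currency of the pipeline: a simple graph (no self-loops,
#' no multi-edges) with signed edges and per-node centrality statistics.
#' Degree counts *distinct neighbors* — in a directed graph a reciprocal
#' edge pair contributes 1 to degree but 1 to each of indegree and
#' outdegree, so a node with 16 in-neighbors and 16 out-neighbors, 15 of
#' them reciprocal, has degree 17. Betweenness is shortest-path betweenness
#' normalized to \[0, 1\] by `(N-1)(N-2)` (directed) or `(N-1)(N-2)/2`
#' (undirected). The k-core index is computed on the undirected projection.
#'
#' @param edges Tibble with columns `from`, `to` and optionally `sign`
#'   ("+" or "-"). Self-loops are dropped; duplicate edges collapsed.
#' @param nodes Optional tibble with `node` and extra attribute columns
#'   (e.g. `regulation`); also supplies isolated nodes.
#' @param directed Whether edges are directed.
#' @return A `gene_network`: list with `graph` (igraph), `nodes` (tibble of
#'   per-node statistics), `edges` (tibble), `directed`.
#' @export
gene_network <- function(edges, nodes = NULL, directed = FALSE) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0 && !all(c("from", "to") %in% names(edges))) {
    abort("`edges` needs columns `from` and `to`.",
          class = "hubgene_domain_error")
  }
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            sign = character())
  }
  if (!"sign" %in% names(edges)) edges$sign <- rep("+", nrow(edges))
  edges <- edges |>
    dplyr::mutate(from = as.character(.data$from), to = as.character(.data$to)) |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::distinct(.data$from, .data$to, .keep_all = TRUE)
  if (!directed) {
    # canonical order so A-B and B-A collapse
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- dplyr::distinct(edges, .data$from, .data$to, .keep_all = TRUE)
  }

  node_ids <- unique(c(edges$from, edges$to))
  if (!is.null(nodes)) {
    nodes <- tibble::as_tibble(nodes)
    if (!"node" %in% names(nodes)) {
      abort("`nodes` needs a `node` column.", class = "hubgene_domain_error")
    }
    nodes$node <- as.character(nodes$node)
    node_ids <- unique(c(nodes$node, node_ids))
  }
  node_ids <- sort(node_ids)

  g <- igraph::graph_from_data_frame(edges, directed = directed,
                                     vertices = node_ids)

  stats <- network_node_stats(g, directed)
  if (!is.null(nodes)) {
    stats <- dplyr::left_join(stats, nodes, by = "node")
  }
  structure(
    list(graph = g, nodes = stats, edges = edges, directed = directed),
    class = "gene_network"
  )
}

# per-node degree / indegree / outdegree / betweenness / k_core
network_node_stats <- function(g, directed) {
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name
  und <- igraph::as_undirected(g, mode = "collapse")
  degree <- igraph::degree(und)
  if (directed) {
    indeg <- igraph::degree(g, mode = "in")
    outdeg <- igraph::degree(g, mode = "out")
  } else {
    indeg <- degree
    outdeg <- degree
  }
  if (n < 3) {
    btw <- rep(0, n)
  } else {
    raw <- igraph::betweenness(g, directed = directed, weights = NA)
    denom <- if (directed) (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
    btw <- raw / denom
  }
  kcore <- igraph::coreness(und)
  tibble::tibble(node = ids, degree = as.integer(degree),
                 indegree = as.integer(indeg),
                 outdegree = as.integer(outdeg),
                 betweenness = unname(btw),
                 k_core = as.integer(kcore)) |>
    dplyr::arrange(.data$node)
}

#' Per-node degree statistics
#'
#' @param network A `gene_network`.
#' @return Tibble with `node`, `degree` (distinct neighbors), `indegree`,
#'   `outdegree`.
#' @export
degree_stats <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  dplyr::select(network$nodes, "node", "degree", "indegree", "outdegree")
}

#' Normalized betweenness centrality
#'
#' @param network A `gene_network`.
#' @return Tibble with `node`, `betweenness` in \[0, 1\].
#' @export
betweenness_stats <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  dplyr::select(network$nodes, "node", "betweenness")
}

#' k-core index per node
#'
#' Iterative pruning on the undirected projection: repeatedly delete nodes
#' of degree < k; a node's core index is the largest k it survives.
#'
#' @param network A `gene_network`.
#' @return Tibble with `node`, `k_core`.
#' @export
k_core_stats <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  dplyr::select(network$nodes, "node", "k_core")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %s, %d nodes, %d edges\n",
              if (x$directed) "directed" else "undirected",
              nrow(x$nodes), nrow(x$edges)))
  print(x$nodes, n = 5)
  invisible(x)
}

#' @method tidy gene_network
#' @export
tidy.gene_network <- function(x, ...) {
  x$nodes
}

#' @method glance gene_network
#' @export
glance.gene_network <- function(x, ...) {
  comp <- igraph::components(x$graph, mode = "weak")
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    directed = x$directed,
    n_components = comp$no,
    max_degree = if (nrow(x$nodes)) max(x$nodes$degree) else 0L,
    max_k_core = if (nrow(x$nodes)) max(x$nodes$k_core) else 0L
  )
}

#' Connected components of a network
#'
#' @param network A `gene_network`.
#' @param min_size Components smaller than this are dropped from the
#'   summary (isolated nodes rarely count as sub-networks).
#' @return Tibble with `component`, `size`, `members` (list column),
#'   ordered by decreasing size.
#' @export
network_components <- function(network, min_size = 2L) {
  stopifnot(inherits(network, "gene_network"))
  comp <- igraph::components(network$graph, mode = "weak")
  if (comp$no == 0L) {
    return(tibble::tibble(component = integer(), size = integer(),
                          members = list()))
  }
  tibble::tibble(node = names(comp$membership),
                 component = unname(comp$membership)) |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(size = dplyr::n(),
                     members = list(sort(.data$node)), .groups = "drop") |>
    dplyr::filter(.data$size >= min_size) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$component) |>
    dplyr::mutate(component = dplyr::row_number())
}

#' Write a network to GraphML
#'
#' Node attributes (`regulation`, `degree`, `indegree`, `outdegree`,
#' `betweenness`, `k_core` and any extra columns) and the edge `sign` are
#' stored as typed GraphML keys; [read_graphml()] restores them.
#'
#' @param network A `gene_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  g <- network$graph
  nd <- network$nodes
  ord <- match(igraph::V(g)$name, nd$node)
  for (col in setdiff(names(nd), "node")) {
    val <- nd[[col]][ord]
    if (is.list(val)) next
    g <- igraph::set_vertex_attr(g, col, value = val)
  }
  if (igraph::ecount(g) > 0 && !is.null(network$edges$sign)) {
    g <- igraph::set_edge_attr(g, "sign", value = network$edges$sign)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file written by [write_graphml()]
#'
#' @param path GraphML file.
#' @return A `gene_network`.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  directed <- igraph::is_directed(g)
  edf <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble::tibble(from = edf$from, to = edf$to,
                          sign = edf$sign %||% rep("+", nrow(edf)))
  vdf <- igraph::as_data_frame(g, what = "vertices")
  keep <- setdiff(names(vdf),
                  c("name", "id", "degree", "indegree", "outdegree",
                    "betweenness", "k_core"))
  nodes <- tibble::tibble(node = vdf$name)
  for (col in keep) nodes[[col]] <- vdf[[col]]
  gene_network(edges, nodes = nodes, directed = directed)
}

#' Write a network's edges as a plain TSV
#'
#' @param network A `gene_network`.
#' @param path Output file; columns `from`, `to`, `sign`, `directed`.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  out <- network$edges
  out$directed <- network$directed
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read an edge TSV written by [write_edge_tsv()]
#'
#' @param path Edge TSV with columns `from`, `to`, `sign`, `directed`.
#' @param nodes Optional node attribute tibble passed to [gene_network()].
#' @return A `gene_network`.
#' @export
read_edge_tsv <- function(path, nodes = NULL) {
  edges <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c",
                                                   directed = "l"))
  directed <- if (nrow(edges)) isTRUE(edges$directed[1]) else FALSE
  gene_network(edges[setdiff(names(edges), "directed")],
               nodes = nodes, directed = directed)
}
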
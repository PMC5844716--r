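# Regulation color of a term: "up"/"down" when significant in exactly one
# direction-specific analysis, "both" when in both (or only the combined
# list).
term_regulation <- function(records) {
  sig <- records[records$significant, c("term_id", "direction")]
  sig |>
    dplyr::distinct() |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(
      regulation = dplyr::case_when(
        all(c("up", "down") %in% .data$direction) ~ "both",
        "up" %in% .data$direction ~ "up",
        "down" %in% .data$direction ~ "down",
        TRUE ~ "both"
      ),
      .groups = "drop"
    )
}

#' Build the GO interaction map of significant terms
#'
#' Restricts the term ancestry DAG to the significantly enriched terms and
#' draws a directed edge from each child (lower-ranking, more specific term)
#' to its nearest significant ancestors — the transitive reduction of the
#' ancestor relation within the significant set, so no edge duplicates a
#' longer significant path. Nodes carry an up/down/both regulation color
#' from the per-direction enrichment results.
#'
#' @param records Enrichment records from [enrich()] (any category; only
#'   significant terms enter the map).
#' @param parent_edges Tibble of `child`, `parent` term pairs; must be
#'   acyclic.
#' @return A directed `gene_network` of significant terms.
#' @export
build_go_map <- function(records, parent_edges) {
  parent_edges <- tibble::as_tibble(parent_edges)
  if (nrow(parent_edges) > 0 &&
      !all(c("child", "parent") %in% names(parent_edges))) {
    abort("`parent_edges` needs columns `child` and `parent`.",
          class = "hubgene_domain_error")
  }

  reg <- term_regulation(records)
  sig_terms <- sort(unique(reg$term_id))
  if (length(sig_terms) == 0L) {
    return(gene_network(tibble::tibble(from = character(), to = character()),
                        directed = TRUE))
  }

  # ancestor closure on the full DAG (cycle check included)
  anc <- ancestor_sets(parent_edges)

  pairs <- purrr::map(sig_terms, function(term) {
    up <- intersect(anc[[term]] %||% character(), sig_terms)
    if (length(up) == 0L) return(NULL)
    # transitive reduction within the significant set: keep B only if no
    # other significant ancestor C of `term` has B among its ancestors
    keep <- purrr::keep(up, function(b) {
      !any(purrr::map_lgl(setdiff(up, b),
                          function(c_) b %in% (anc[[c_]] %||% character())))
    })
    tibble::tibble(from = term, to = keep)
  }) |> purrr::list_rbind()

  if (is.null(pairs)) pairs <- tibble::tibble(from = character(),
                                              to = character())
  nodes <- tibble::tibble(node = sig_terms) |>
    dplyr::left_join(reg, by = c(node = "term_id"))
  gene_network(pairs, nodes = nodes, directed = TRUE)
}

# child -> set of all ancestors; errors (naming a member) on cycles
ancestor_sets <- function(parent_edges) {
  if (nrow(parent_edges) == 0L) return(list())
  parent_edges <- dplyr::distinct(parent_edges, .data$child, .data$parent)
  g <- igraph::graph_from_data_frame(parent_edges, directed = TRUE)
  if (!igraph::is_dag(g)) {
    scc <- igraph::components(g, mode = "strong")
    cyc_comp <- which(scc$csize > 1)[1]
    member <- igraph::V(g)$name[scc$membership == cyc_comp][1]
    abort(sprintf("`parent_edges` contains a cycle (involving term `%s`).",
                  member),
          class = "hubgene_domain_error")
  }
  ids <- igraph::V(g)$name
  reach <- igraph::ego(g, order = igraph::vcount(g), mode = "out",
                       mindist = 1)
  setNames(lapply(reach, function(v) v$name), ids)
}

#' Build the significant-pathway interaction network
#'
#' Nodes are the significantly enriched pathways (colored up/down/both);
#' an undirected edge joins two pathways when the curated pathway-pathway
#' adjacency lists them as interacting and both are significant.
#'
#' @param records Enrichment records from [enrich()] for the pathway
#'   category.
#' @param adjacency Tibble of pathway id pairs (`from`, `to`).
#' @return An undirected `gene_network` with per-node degree.
#' @export
build_pathway_network <- function(records, adjacency) {
  adjacency <- tibble::as_tibble(adjacency)
  if (nrow(adjacency) > 0 && !all(c("from", "to") %in% names(adjacency))) {
    abort("`adjacency` needs columns `from` and `to`.",
          class = "hubgene_domain_error")
  }
  reg <- term_regulation(records)
  sig <- reg$term_id
  keep <- adjacency |>
    dplyr::filter(.data$from %in% sig, .data$to %in% sig)
  nodes <- tibble::tibble(node = sort(sig)) |>
    dplyr::left_join(reg, by = c(node = "term_id"))
  gene_network(keep, nodes = nodes, directed = FALSE)
}

#' Rank pathways by degree
#'
#' @param network Pathway network from [build_pathway_network()].
#' @return Tibble ordered by descending degree, ties broken by pathway id;
#'   the first row is the hub pathway.
#' @export
hub_pathway <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  network$nodes |>
    dplyr::select("node", "degree") |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$node)
}

#' Derive a pathway adjacency from shared gene membership
#'
#' When no curated pathway-interaction file is available, two pathways are
#' declared adjacent when they share at least `min_shared` member genes.
#'
#' @param gene_sets Gene-set tibble (`term_id`, `gene_id`), pathway
#'   category already selected.
#' @param min_shared Minimum shared genes (default 1).
#' @return Tibble of `from`, `to` pathway pairs (from < to).
#' @export
shared_gene_adjacency <- function(gene_sets, min_shared = 1L) {
  memb <- dplyr::distinct(gene_sets, .data$term_id, .data$gene_id)
  pairs <- dplyr::inner_join(memb, memb, by = "gene_id",
                             relationship = "many-to-many") |>
    dplyr::filter(.data$term_id.x < .data$term_id.y) |>
    dplyr::count(.data$term_id.x, .data$term_id.y, name = "shared") |>
    dplyr::filter(.data$shared >= min_shared)
  tibble::tibble(from = pairs$term_id.x, to = pairs$term_id.y)
}
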
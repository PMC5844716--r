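#' Nominate hub genes by intersecting evidence streams
#'
#' Formalizes the "combined results" decision as an explicit evidence
#' count over three streams, per differential gene:
#'
#' * **pathway**: member of at least one significantly enriched pathway;
#' * **signal**: betweenness rank in the signal network within the top
#'   `top_k`;
#' * **coexpression**: k-core at or above `k_core_min` in either group
#'   network, or a status change between the group networks.
#'
#' A gene is called a hub when at least `min_evidence` streams fire.
#'
#' @param differential Selected differential genes (`gene_id`, `trend`).
#' @param pathway_records Enrichment records for the pathway category
#'   (from [enrich()]).
#' @param gene_sets Gene-set membership tibble used for the pathway
#'   analysis (`term_id`, `category`, `gene_id`).
#' @param signal_rank Output of [rank_hub_genes()].
#' @param coexpr_comparison Output of [compare_group_networks()].
#' @param top_k Betweenness rank cutoff for the signal stream (default 10,
#'   the length of a typical printed hub table).
#' @param k_core_min Minimum k-core for the co-expression stream.
#' @param min_evidence Streams required to call a hub (default 2).
#' @return A `hub_report` tibble: per gene the stream flags, the supporting
#'   pathway ids (list column), signal betweenness rank, per-group k-cores,
#'   `evidence_count` and `hub_call`, ordered by evidence count then signal
#'   rank then gene id.
#' @export
integrate_hub_evidence <- function(differential, pathway_records, gene_sets,
                                   signal_rank, coexpr_comparison,
                                   top_k = 10L, k_core_min = 2L,
                                   min_evidence = 2L) {
  check_count(top_k, "top_k", min = 1L)
  check_count(k_core_min, "k_core_min", min = 0L)
  check_count(min_evidence, "min_evidence", min = 1L)
  de <- unique(differential$gene_id)

  extra_sig <- setdiff(signal_rank$gene_id, de)
  extra_cox <- setdiff(coexpr_comparison$gene_id, de)
  if (length(extra_sig) || length(extra_cox)) {
    abort(paste0(
      "evidence tables reference genes outside the differential set: ",
      paste(head(unique(c(extra_sig, extra_cox)), 10), collapse = ", ")),
      class = "hubgene_domain_error")
  }

  sig_pathways <- unique(
    pathway_records$term_id[pathway_records$significant])
  memb <- gene_sets |>
    dplyr::filter(.data$term_id %in% sig_pathways,
                  .data$gene_id %in% de) |>
    dplyr::distinct(.data$gene_id, .data$term_id) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(pathways = list(sort(.data$term_id)), .groups = "drop")

  rank_tbl <- signal_rank |>
    dplyr::mutate(signal_rank = dplyr::row_number()) |>
    dplyr::select("gene_id", "signal_rank", signal_betweenness = "betweenness")

  out <- tibble::tibble(gene_id = sort(de)) |>
    dplyr::left_join(memb, by = "gene_id") |>
    dplyr::left_join(rank_tbl, by = "gene_id") |>
    dplyr::left_join(
      dplyr::select(coexpr_comparison, "gene_id", "k_core_ctrl",
                    "k_core_exp", "status_change"),
      by = "gene_id") |>
    dplyr::mutate(
      pathways = purrr::map(.data$pathways, ~ .x %||% character()),
      in_significant_pathway = purrr::map_int(.data$pathways, length) > 0,
      signal_top = !is.na(.data$signal_rank) & .data$signal_rank <= top_k,
      k_core_ctrl = dplyr::coalesce(.data$k_core_ctrl, 0L),
      k_core_exp = dplyr::coalesce(.data$k_core_exp, 0L),
      status_change = dplyr::coalesce(.data$status_change, FALSE),
      coexpr_core = pmax(.data$k_core_ctrl, .data$k_core_exp) >= k_core_min |
        .data$status_change,
      evidence_count = .data$in_significant_pathway + .data$signal_top +
        .data$coexpr_core,
      hub_call = .data$evidence_count >= min_evidence
    ) |>
    dplyr::arrange(dplyr::desc(.data$evidence_count), .data$signal_rank,
                   .data$gene_id)
  class(out) <- c("hub_report", class(out))
  attr(out, "config") <- list(top_k = top_k, k_core_min = k_core_min,
                              min_evidence = min_evidence)
  out
}

#' @method glance hub_report
#' @export
glance.hub_report <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n_candidates = nrow(x),
    n_hubs = sum(x$hub_call),
    top_k = cfg$top_k,
    k_core_min = cfg$k_core_min,
    min_evidence = cfg$min_evidence
  )
}

#' Called hub genes from a report
#'
#' @param report A `hub_report`.
#' @return Character vector of hub gene ids (report order).
#' @export
hub_genes <- function(report) {
  stopifnot(inherits(report, "hub_report"))
  report$gene_id[report$hub_call]
}
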
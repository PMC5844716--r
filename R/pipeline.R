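#' Pipeline configuration
#'
#' Every stage threshold has a named key with its conventional default:
#' differential cutoffs `p_cut`/`fdr_cut` 0.05/0.05, co-expression gates
#' `|R| >= 0.8` and p < 0.05, betweenness top-K 10, hub evidence minimum 2.
#'
#' @param sim A [sim_config()] describing the synthetic inputs, or `NULL`
#'   when file inputs are supplied to [run_pipeline()].
#' @param p_cut,fdr_cut Differential and enrichment significance cutoffs.
#' @param r_threshold,coexpr_p Co-expression edge gates.
#' @param top_k,k_core_min,min_evidence Hub-integration thresholds.
#' @param min_component_size Minimum GO-map component size counted as a
#'   sub-network.
#' @param qpcr_reference qPCR reference gene id.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            p_cut = 0.05, fdr_cut = 0.05,
                            r_threshold = 0.8, coexpr_p = 0.05,
                            top_k = 10L, k_core_min = 2L,
                            min_evidence = 2L,
                            min_component_size = 2L,
                            qpcr_reference = "Actb") {
  check_proportion(p_cut, "p_cut")
  check_proportion(fdr_cut, "fdr_cut")
  check_proportion(coexpr_p, "coexpr_p")
  if (!is.numeric(r_threshold) || r_threshold < 0 || r_threshold > 1) {
    abort("`r_threshold` must lie in [0, 1].", class = "hubgene_config_error")
  }
  structure(
    list(sim = sim, p_cut = p_cut, fdr_cut = fdr_cut,
         r_threshold = r_threshold, coexpr_p = coexpr_p,
         top_k = check_count(top_k, "top_k", 1L),
         k_core_min = check_count(k_core_min, "k_core_min"),
         min_evidence = check_count(min_evidence, "min_evidence", 1L),
         min_component_size = check_count(min_component_size,
                                          "min_component_size", 1L),
         qpcr_reference = qpcr_reference),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys match the [pipeline_config()] arguments; a `sim` block
#' matches [sim_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  if (!is.null(sim_args$hub_spec)) {
    sim_args$hub_spec <- lapply(sim_args$hub_spec, function(h) {
      h$gene <- h$gene %||% NA_character_
      h
    })
  }
  sim <- do.call(sim_config, sim_args)
  args <- raw[setdiff(names(raw), "sim")]
  do.call(pipeline_config, c(list(sim = sim), args))
}

#' Simulate the full input bundle for one study
#'
#' Expression matrix, group labels, GO and pathway gene sets, a term-parent
#' DAG, pathway adjacency, curated interaction edges and a qPCR Ct table,
#' all derived deterministically from the config seed.
#'
#' @param config A [sim_config()].
#' @param n_qpcr_genes Validation genes in the Ct table (planted hub genes
#'   plus top differential genes).
#' @param qpcr_noise_sd Ct noise in cycles.
#' @return Named list of every input plus `truth`.
#' @export
simulate_dataset <- function(config, n_qpcr_genes = 14L,
                             qpcr_noise_sd = 0.05) {
  sim <- simulate_expression(config)
  go <- simulate_annotations(config, sim$truth, category = "GO")
  kegg <- simulate_annotations(config, sim$truth, category = "KEGG")
  term_parents <- simulate_term_parents(config, unique(go$gene_sets$term_id))
  pathway_adjacency <- simulate_pathway_adjacency(
    config, unique(kegg$gene_sets$term_id))
  interaction_edges <- simulate_interaction_edges(config, sim$truth)

  qpcr_pool <- sim$truth$de_genes
  qpcr_genes <- unique(c(sim$truth$hub_genes,
                         qpcr_pool$gene_id))[seq_len(
                           min(n_qpcr_genes, nrow(qpcr_pool)))]
  folds <- setNames(
    qpcr_pool$fold_change[match(qpcr_genes, qpcr_pool$gene_id)],
    qpcr_genes)
  folds <- folds[!is.na(folds)]
  ct_table <- simulate_ct_table(folds, n_replicates = config$n_samples_per_group,
                                noise_sd = qpcr_noise_sd,
                                seed = config$seed + 5000L)

  truth <- sim$truth
  truth$enriched_go_terms <- go$enriched_term_ids
  truth$enriched_pathways <- kegg$enriched_term_ids

  list(expr = sim$expr, groups = sim$groups,
       gene_sets_go = go$gene_sets, gene_sets_pathway = kegg$gene_sets,
       term_parents = term_parents, pathway_adjacency = pathway_adjacency,
       interaction_edges = interaction_edges, ct_table = ct_table,
       truth = truth)
}

#' Write a simulated input bundle to a directory
#'
#' @param dataset From [simulate_dataset()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_expression_tsv(dataset$expr, p("expression.tsv"))
  write_groups_tsv(dataset$groups, p("groups.tsv"))
  write_gmt(dataset$gene_sets_go, p("go.gmt"))
  write_gmt(dataset$gene_sets_pathway, p("pathway.gmt"))
  write_pairs_tsv(dataset$term_parents, p("term_parents.tsv"))
  write_pairs_tsv(dataset$pathway_adjacency, p("pathway_adjacency.tsv"))
  write_interaction_tsv(dataset$interaction_edges, p("interactions.tsv"))
  write_ct_csv(dataset$ct_table, p("ct.csv"))
  write_truth_json(dataset$truth, p("truth.json"))
  invisible(outdir)
}

#' Run the full hub-gene discovery pipeline
#'
#' simulate (or accept) inputs, screen differential genes, score GO and
#' pathway over-representation, build the GO map, pathway, signal and
#' per-group co-expression networks, intersect the evidence into a hub
#' report, and score qPCR concordance. Deterministic under a fixed config.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, every stage output and a
#'   `report.json` are written there.
#' @param dataset Optional pre-built input bundle (as from
#'   [simulate_dataset()]); defaults to simulating from `config$sim`.
#' @return A list of stage results plus `report` (the summary list).
#' @export
run_pipeline <- function(config, outdir = NULL, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  note <- function(msg) log_lines <<- c(log_lines, msg)

  withCallingHandlers({
    if (is.null(dataset)) {
      if (is.null(config$sim)) {
        abort("no `dataset` supplied and `config$sim` is NULL.",
              class = "hubgene_config_error")
      }
      dataset <- simulate_dataset(config$sim)
    }

    de_all <- diff_expression(dataset$expr, dataset$groups)
    de_sel <- select_differential(de_all, config$p_cut, config$fdr_cut)

    enr_go <- enrich(dataset$gene_sets_go, de_sel,
                     p_cut = config$p_cut, fdr_cut = config$fdr_cut)
    enr_path <- enrich(dataset$gene_sets_pathway, de_sel,
                       p_cut = config$p_cut, fdr_cut = config$fdr_cut)

    go_map <- build_go_map(enr_go, dataset$term_parents)
    go_components <- network_components(go_map, config$min_component_size)

    path_net <- build_pathway_network(enr_path, dataset$pathway_adjacency)
    path_rank <- hub_pathway(path_net)

    signal_net <- build_signal_network(de_sel, dataset$interaction_edges)
    signal_rank <- rank_hub_genes(signal_net)

    sig_go_terms <- unique(enr_go$term_id[enr_go$significant])
    coexpr_genes <- dataset$gene_sets_go |>
      dplyr::filter(.data$term_id %in% sig_go_terms,
                    .data$gene_id %in% de_sel$gene_id) |>
      dplyr::pull(.data$gene_id) |>
      unique()
    if (length(coexpr_genes) < 2) {
      note("co-expression: no significant-GO gene subset; using all differential genes")
      coexpr_genes <- de_sel$gene_id
    }
    net_ctrl <- build_coexpression_network(
      dataset$expr, dataset$groups, "control", genes = coexpr_genes,
      r_threshold = config$r_threshold, p_threshold = config$coexpr_p,
      regulation = de_sel)
    net_exp <- build_coexpression_network(
      dataset$expr, dataset$groups, "experimental", genes = coexpr_genes,
      r_threshold = config$r_threshold, p_threshold = config$coexpr_p,
      regulation = de_sel)
    coexpr_cmp <- compare_group_networks(net_ctrl, net_exp)

    hub_report <- integrate_hub_evidence(
      de_sel, enr_path, dataset$gene_sets_pathway, signal_rank, coexpr_cmp,
      top_k = config$top_k, k_core_min = config$k_core_min,
      min_evidence = config$min_evidence)

    qpcr <- NULL
    qpcr_concordance <- NULL
    if (!is.null(dataset$ct_table)) {
      qpcr <- ddct_ratios(dataset$ct_table,
                          reference = config$qpcr_reference)
      qpcr_concordance <- concordance(de_all, qpcr)
    }

    report <- list(
      n_genes = nrow(dataset$expr),
      n_differential = nrow(de_sel),
      n_up = sum(de_sel$trend == "up"),
      n_down = sum(de_sel$trend == "down"),
      max_fold_change = if (nrow(de_sel)) max(de_sel$fold_change) else NA,
      n_significant_go_up = sum(enr_go$significant &
                                  enr_go$direction == "up"),
      n_significant_go_down = sum(enr_go$significant &
                                    enr_go$direction == "down"),
      n_significant_pathways = length(
        unique(enr_path$term_id[enr_path$significant])),
      n_go_subnetworks = nrow(go_components),
      hub_pathway = if (nrow(path_rank)) path_rank$node[1] else NA,
      top_betweenness_gene = if (nrow(signal_rank))
        signal_rank$gene_id[1] else NA,
      hub_genes = hub_genes(hub_report),
      qpcr_concordance = if (!is.null(qpcr_concordance))
        attr(qpcr_concordance, "concordance") else NA,
      config = config[setdiff(names(config), "sim")],
      sim = if (!is.null(config$sim)) unclass(config$sim) else NULL,
      log = log_lines
    )

    result <- list(dataset = dataset, differential = de_all,
                   selected = de_sel, enrichment_go = enr_go,
                   enrichment_pathway = enr_path, go_map = go_map,
                   go_components = go_components,
                   pathway_network = path_net, pathway_rank = path_rank,
                   signal_network = signal_net, signal_rank = signal_rank,
                   coexpr_control = net_ctrl, coexpr_experimental = net_exp,
                   coexpr_comparison = coexpr_cmp, hub_report = hub_report,
                   qpcr = qpcr, qpcr_concordance = qpcr_concordance,
                   report = report)

    if (!is.null(outdir)) write_pipeline_outputs(result, outdir, log_lines)
    result
  }, message = function(m) {
    note(sub("\n$", "", conditionMessage(m)))
    invokeRestart("muffleMessage")
  }, warning = function(w) {
    note(paste0("WARN: ", conditionMessage(w)))
    invokeRestart("muffleWarning")
  })
}

write_pipeline_outputs <- function(result, outdir, log_lines) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_dataset(result$dataset, file.path(outdir, "inputs"))
  write_differential_tsv(result$selected, p("differential.tsv"))
  readr::write_tsv(volcano_coordinates(result$differential), p("volcano.tsv"))
  readr::write_tsv(result$enrichment_go, p("enrichment_go.tsv"))
  readr::write_tsv(result$enrichment_pathway, p("enrichment_pathway.tsv"))
  write_graphml(result$go_map, p("go_map.graphml"))
  readr::write_tsv(
    result$go_components |>
      dplyr::mutate(members = purrr::map_chr(.data$members, paste,
                                             collapse = ";")),
    p("go_subnetworks.tsv"))
  write_graphml(result$pathway_network, p("pathway_network.graphml"))
  write_graphml(result$signal_network, p("signal_network.graphml"))
  readr::write_tsv(result$signal_rank, p("hub_rank.tsv"))
  write_graphml(result$coexpr_control, p("coexpr_control.graphml"))
  write_graphml(result$coexpr_experimental, p("coexpr_experimental.graphml"))
  readr::write_tsv(
    result$coexpr_comparison |>
      dplyr::mutate(dplyr::across(dplyr::where(is.list),
                                  ~ purrr::map_chr(.x, paste, collapse = ";"))),
    p("coexpr_comparison.tsv"))
  readr::write_tsv(
    result$hub_report |>
      dplyr::mutate(pathways = purrr::map_chr(.data$pathways, paste,
                                              collapse = ";")),
    p("hub_report.tsv"))
  if (!is.null(result$qpcr)) {
    readr::write_tsv(result$qpcr, p("qpcr_ratios.tsv"))
  }
  jsonlite::write_json(result$report, p("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, p("run.log"))
  invisible(outdir)
}
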
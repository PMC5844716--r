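#' Build a per-group Pearson co-expression network
#'
#' Correlates every pair of the selected genes across the samples of one
#' group (on log2 intensities by default) and draws an undirected edge for
#' each pair passing both a magnitude gate `|R| >= r_threshold` and a
#' two-sided correlation-test p-value below `p_threshold`
#' (t = R * sqrt(df / (1 - R^2)), df = n_samples - 2). Edge sign is the
#' correlation sign: "+" positive regulation, "-" negative. Nodes carry
#' degree and k-core.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param groups Tibble with `sample_id`, `group`.
#' @param group Which group's samples to use.
#' @param genes Gene subset (typically the genes of significant GO terms);
#'   defaults to all genes in `expr`.
#' @param r_threshold Minimum absolute Pearson correlation (default 0.8 —
#'   with 3 replicates a pure p-gate is meaningless, so the magnitude gate
#'   is mandatory).
#' @param p_threshold Two-sided correlation-test p cutoff (default 0.05).
#' @param log2_scale Correlate log2 intensities (default TRUE).
#' @param regulation Optional tibble (`gene_id`, `trend`) to color nodes.
#' @return An undirected `gene_network`.
#' @export
build_coexpression_network <- function(expr, groups, group,
                                       genes = NULL,
                                       r_threshold = 0.8,
                                       p_threshold = 0.05,
                                       log2_scale = TRUE,
                                       regulation = NULL) {
  samples <- group_samples(groups, group)
  if (length(samples) < 3L) {
    abort(sprintf(
      "group `%s` has %d samples; >= 3 are required (correlation df <= 0).",
      group, length(samples)), class = "hubgene_domain_error")
  }
  check_proportion(p_threshold, "p_threshold")
  if (is.null(genes)) genes <- expr$gene_id
  genes <- intersect(expr$gene_id, unique(genes))
  sub <- expr[match(genes, expr$gene_id), c("gene_id", samples)]
  mat <- as.matrix(sub[-1])
  if (log2_scale) mat <- log2(mat)
  rownames(mat) <- sub$gene_id

  keep_var <- apply(mat, 1, sd) > 0
  mat <- mat[keep_var, , drop = FALSE]
  edges <- tibble::tibble(from = character(), to = character(),
                          sign = character())
  if (nrow(mat) >= 2) {
    cm <- cor(t(mat))
    n <- ncol(mat)
    dfree <- n - 2
    r <- cm[upper.tri(cm)]
    idx <- which(upper.tri(cm), arr.ind = TRUE)
    tstat <- r * sqrt(dfree / pmax(1 - r^2, .Machine$double.eps))
    pval <- 2 * pt(-abs(tstat), df = dfree)
    pval[abs(r) >= 1 - 1e-12] <- 0  # exact collinearity
    pass <- abs(r) >= r_threshold & pval < p_threshold
    if (any(pass)) {
      edges <- tibble::tibble(
        from = rownames(cm)[idx[pass, 1]],
        to = rownames(cm)[idx[pass, 2]],
        sign = ifelse(r[pass] >= 0, "+", "-")
      )
    }
  }
  nodes <- tibble::tibble(node = genes)
  if (!is.null(regulation)) {
    nodes <- dplyr::left_join(
      nodes,
      dplyr::distinct(regulation, .data$gene_id, .data$trend) |>
        dplyr::rename(node = "gene_id", regulation = "trend"),
      by = "node")
  }
  gene_network(edges, nodes = nodes, directed = FALSE)
}

#' Compare co-expression networks between groups
#'
#' For every gene in either network, reports degree and k-core in each
#' group, the correlation partners gained and lost (split by edge sign),
#' and a status-change flag: the gene's core index moved by at least
#' `k_core_delta` between groups (covering hubs present in only one group,
#' whose other-group core is 0).
#'
#' @param net_ctrl,net_exp Control and experimental `gene_network`s from
#'   [build_coexpression_network()].
#' @param k_core_delta Minimum |k-core difference| to flag a status change.
#' @return Tibble keyed by `gene_id` with `degree_ctrl`, `degree_exp`,
#'   `k_core_ctrl`, `k_core_exp`, list columns
#'   `gained_pos`/`gained_neg`/`lost_pos`/`lost_neg`, and `status_change`.
#' @export
compare_group_networks <- function(net_ctrl, net_exp, k_core_delta = 1L) {
  stopifnot(inherits(net_ctrl, "gene_network"),
            inherits(net_exp, "gene_network"))
  partners <- function(net, gene, wanted_sign) {
    e <- net$edges[net$edges$sign == wanted_sign, ]
    sort(unique(c(e$to[e$from == gene], e$from[e$to == gene])))
  }
  all_genes <- sort(union(net_ctrl$nodes$node, net_exp$nodes$node))
  look <- function(net, col) {
    v <- setNames(net$nodes[[col]], net$nodes$node)[all_genes]
    ifelse(is.na(v), 0L, v)
  }
  res <- tibble::tibble(
    gene_id = all_genes,
    degree_ctrl = as.integer(look(net_ctrl, "degree")),
    degree_exp = as.integer(look(net_exp, "degree")),
    k_core_ctrl = as.integer(look(net_ctrl, "k_core")),
    k_core_exp = as.integer(look(net_exp, "k_core"))
  )
  res$gained_pos <- purrr::map(all_genes, function(g)
    setdiff(partners(net_exp, g, "+"), partners(net_ctrl, g, "+")))
  res$gained_neg <- purrr::map(all_genes, function(g)
    setdiff(partners(net_exp, g, "-"), partners(net_ctrl, g, "-")))
  res$lost_pos <- purrr::map(all_genes, function(g)
    setdiff(partners(net_ctrl, g, "+"), partners(net_exp, g, "+")))
  res$lost_neg <- purrr::map(all_genes, function(g)
    setdiff(partners(net_ctrl, g, "-"), partners(net_exp, g, "-")))
  res$status_change <- abs(res$k_core_exp - res$k_core_ctrl) >= k_core_delta
  res
}
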
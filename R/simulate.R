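#' Simulation configuration
#'
#' Parameters of the synthetic two-group expression study. Defaults mirror
#' a small-replicate brain microarray design: 3 biological replicates per
#' group, ~10% of genes differential with geometric-mean fold changes
#' spanning 2 to 47.26 (the span of a typical top table), about 40% of the
#' differential genes up-regulated, and log-normal intensity noise.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_group Replicates per group (default 3).
#' @param de_fraction Fraction of genes that are truly differential.
#' @param fold_change_range Range of true fold changes (lower bound > 1);
#'   drawn uniformly on the log2 scale.
#' @param up_fraction Fraction of differential genes that are up-regulated.
#' @param noise_sd_log2 SD of log2 intensity noise per (gene, sample).
#' @param baseline_log2_mean,baseline_log2_sd Distribution of control-group
#'   log2 geometric means across genes.
#' @param n_terms Number of simulated gene sets.
#' @param enriched_terms How many terms get planted over-representation.
#' @param enrichment_odds Odds multiplier favoring differential genes when
#'   an enriched term draws members. The default (20, with the minimum term
#'   size of 15) is set so the smallest planted term's expected differential
#'   count clears the Fisher/BH detection boundary with a wide margin: with
#'   10% of genes differential, a weight of 20 makes ~69% of a planted
#'   term's members differential, versus ~10-13% expected under the null.
#' @param term_size_range Member count range per term.
#' @param hub_spec List of `list(gene =, n_spokes =, strength =)` planted
#'   network/co-expression hubs; genes are picked from the differential set
#'   when `gene` is `NA`.
#' @param n_random_edges Background interaction edges among differential
#'   genes.
#' @param seed Integer seed; fully determines every simulated object.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_samples_per_group = 3L,
                       de_fraction = 0.1,
                       fold_change_range = c(2.0, 47.26),
                       up_fraction = 0.4,
                       noise_sd_log2 = 0.35,
                       baseline_log2_mean = 7,
                       baseline_log2_sd = 1.5,
                       n_terms = 50L,
                       enriched_terms = 10L,
                       enrichment_odds = 20,
                       term_size_range = c(15L, 40L),
                       hub_spec = default_hub_spec(),
                       n_random_edges = 150L,
                       seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes", min = 1L),
    n_samples_per_group = check_count(n_samples_per_group,
                                      "n_samples_per_group", min = 2L),
    de_fraction = check_proportion(de_fraction, "de_fraction"),
    fold_change_range = fold_change_range,
    up_fraction = check_proportion(up_fraction, "up_fraction"),
    noise_sd_log2 = noise_sd_log2,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    n_terms = check_count(n_terms, "n_terms"),
    enriched_terms = check_count(enriched_terms, "enriched_terms"),
    enrichment_odds = enrichment_odds,
    term_size_range = term_size_range,
    hub_spec = hub_spec,
    n_random_edges = check_count(n_random_edges, "n_random_edges"),
    seed = check_count(seed, "seed")
  )
  if (length(fold_change_range) != 2L || fold_change_range[1] <= 1 ||
      diff(fold_change_range) < 0) {
    abort("`fold_change_range` must be an increasing pair with lower bound > 1.",
          class = "hubgene_config_error")
  }
  if (!is.numeric(noise_sd_log2) || noise_sd_log2 < 0) {
    abort("`noise_sd_log2` must be >= 0.", class = "hubgene_config_error")
  }
  if (baseline_log2_sd < 0) {
    abort("`baseline_log2_sd` must be >= 0.", class = "hubgene_config_error")
  }
  if (cfg$enriched_terms > cfg$n_terms) {
    abort("`enriched_terms` cannot exceed `n_terms`.",
          class = "hubgene_config_error")
  }
  for (h in cfg$hub_spec) {
    if (!all(c("n_spokes", "strength") %in% names(h))) {
      abort("each `hub_spec` entry needs `n_spokes` and `strength`.",
            class = "hubgene_config_error")
    }
    if (h$n_spokes >= cfg$n_genes) {
      abort("`hub_spec` n_spokes must be smaller than n_genes.",
            class = "hubgene_config_error")
    }
    check_proportion(h$strength, "hub_spec strength")
  }
  structure(cfg, class = "sim_config")
}

#' Default planted hubs: three hubs, 16 spokes each, strong latent
#' correlation.
#' @export
default_hub_spec <- function() {
  list(
    list(gene = NA_character_, n_spokes = 16L, strength = 0.9),
    list(gene = NA_character_, n_spokes = 12L, strength = 0.9),
    list(gene = NA_character_, n_spokes = 8L, strength = 0.9)
  )
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Simulate a two-group expression matrix with planted structure
#'
#' Intensities are `2^(log2 mean + noise)` (log-normal), so group geometric
#' means and their ratios behave exactly like microarray fold changes.
#' Differential genes have the experimental-group log2 mean shifted by
#' +/- log2(true fold change). Each planted hub and its spokes additionally
#' share a per-sample latent factor with loading `sqrt(strength)`, inducing
#' pairwise Pearson correlation `strength` in expectation within the block
#' while leaving the total noise variance at `noise_sd_log2^2`.
#'
#' @param config A [sim_config()].
#' @return List with `expr` (tibble `gene_id` + sample columns), `groups`
#'   (tibble `sample_id`, `group`), and `truth` — a list with `de_genes`
#'   (tibble `gene_id`, `trend`, `fold_change`), `hub_blocks` (list of
#'   gene-id vectors, hub first), `hub_genes`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  m <- config$n_samples_per_group
  ids <- gene_ids(n)
  samples <- c(sprintf("ctrl_%d", seq_len(m)), sprintf("exp_%d", seq_len(m)))
  group <- rep(c("control", "experimental"), each = m)

  base <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  n_de <- round(n * config$de_fraction)
  de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer()
  n_up <- round(n_de * config$up_fraction)
  up_idx <- if (n_up > 0) de_idx[sort(sample.int(n_de, n_up))] else integer()
  lfc <- numeric(n)
  if (n_de > 0) {
    mag <- 2^runif(n_de, log2(config$fold_change_range[1]),
                   log2(config$fold_change_range[2]))
    lfc[de_idx] <- log2(mag) * ifelse(de_idx %in% up_idx, 1, -1)
  }

  # hub blocks: hub + spokes share a latent factor
  hub_blocks <- list()
  taken <- integer()
  pool <- if (n_de > 0) de_idx else seq_len(n)
  for (h in config$hub_spec) {
    avail <- setdiff(pool, taken)
    # hub + n_spokes + 1 spokes: the extra spoke lets the hub have one
    # incoming-only and one outgoing-only neighbor, the reciprocal-edge
    # bookkeeping behind a (degree, indegree, outdegree) triple of
    # (n_spokes + 1, n_spokes, n_spokes)
    if (length(avail) < h$n_spokes + 2L) {
      abort("not enough unassigned genes for `hub_spec`; lower n_spokes or raise n_genes/de_fraction.",
            class = "hubgene_config_error")
    }
    if (is.na(h$gene)) {
      block <- avail[seq_len(h$n_spokes + 2L)]
    } else {
      hub_i <- match(h$gene, ids)
      if (is.na(hub_i)) {
        abort(sprintf("hub gene `%s` not in the simulated universe.", h$gene),
              class = "hubgene_config_error")
      }
      block <- c(hub_i, setdiff(avail, hub_i)[seq_len(h$n_spokes + 1L)])
    }
    taken <- c(taken, block)
    hub_blocks <- c(hub_blocks, list(block))
  }

  log2_mean <- matrix(base, n, 2 * m)
  log2_mean[, group == "experimental"] <-
    log2_mean[, group == "experimental"] + lfc

  noise <- matrix(rnorm(n * 2 * m, 0, config$noise_sd_log2), n, 2 * m)
  for (k in seq_along(hub_blocks)) {
    block <- hub_blocks[[k]]
    w <- sqrt(config$hub_spec[[k]]$strength)
    f <- rnorm(2 * m)  # latent factor per sample
    noise[block, ] <- config$noise_sd_log2 *
      (w * matrix(f, length(block), 2 * m, byrow = TRUE) +
         sqrt(1 - w^2) * matrix(rnorm(length(block) * 2 * m), length(block)))
  }

  mat <- 2^(log2_mean + noise)
  expr <- tibble::as_tibble(as.data.frame(mat)) |>
    setNames(samples) |>
    dplyr::mutate(gene_id = ids, .before = 1)

  truth <- list(
    de_genes = tibble::tibble(
      gene_id = ids[de_idx],
      trend = ifelse(de_idx %in% up_idx, "up", "down"),
      fold_change = 2^lfc[de_idx]
    ),
    hub_blocks = lapply(hub_blocks, function(b) ids[b]),
    hub_genes = vapply(hub_blocks, function(b) ids[b[1]], character(1))
  )
  list(expr = expr,
       groups = tibble::tibble(sample_id = samples, group = group),
       truth = truth)
}

#' Simulate gene-set annotations with planted over-representation
#'
#' The first `enriched_terms` terms draw members with sampling weight
#' `enrichment_odds` on true differential genes (weight 1 elsewhere);
#' remaining terms draw uniformly.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_expression()].
#' @param category Category label for the terms ("GO" or "KEGG").
#' @return List with `gene_sets` (tibble `term_id`, `name`, `category`,
#'   `gene_id`) and `enriched_term_ids`.
#' @export
simulate_annotations <- function(config, truth, category = "GO") {
  stopifnot(inherits(config, "sim_config"))
  # distinct substream per category so GO and pathway sets differ
  set.seed(config$seed + if (category == "GO") 1000L else 1500L)
  ids <- gene_ids(config$n_genes)
  de <- truth$de_genes$gene_id
  weights <- ifelse(ids %in% de, config$enrichment_odds, 1)
  sizes <- sample(seq(config$term_size_range[1], config$term_size_range[2]),
                  config$n_terms, replace = TRUE)
  if (any(sizes > config$n_genes)) {
    abort("term size exceeds gene universe.", class = "hubgene_config_error")
  }
  prefix <- if (category == "GO") "GO:%07d" else "path%03d"
  term_ids <- sprintf(prefix, seq_len(config$n_terms))
  sets <- purrr::imap(term_ids, function(tid, i) {
    members <- if (i <= config$enriched_terms) {
      sample(ids, sizes[i], prob = weights)
    } else {
      sample(ids, sizes[i])
    }
    tibble::tibble(term_id = tid,
                   name = paste0(category, " term ", i),
                   category = category,
                   gene_id = sort(members))
  }) |> purrr::list_rbind()
  list(gene_sets = sets,
       enriched_term_ids = term_ids[seq_len(config$enriched_terms)])
}

#' Simulate a curated signed interaction edge list
#'
#' Each planted hub receives `n_spokes` incoming and `n_spokes` outgoing
#' edges to its spoke genes (all but one reciprocal, so the hub's distinct-
#' neighbor degree is `n_spokes + 1`), plus sparse random background edges
#' among differential genes — a star-dominated topology in which the hub's
#' betweenness is maximal.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_expression()].
#' @return Tibble of directed edges (`from`, `to`, `sign`).
#' @export
simulate_interaction_edges <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2000L)
  edges <- list()
  for (k in seq_along(truth$hub_blocks)) {
    block <- truth$hub_blocks[[k]]
    hub <- block[1]
    spokes <- block[-1]              # n_spokes + 1 genes
    n_s <- length(spokes) - 1L
    in_sources <- spokes[seq_len(n_s)]            # first spoke in-only
    out_targets <- spokes[seq_len(n_s) + 1L]      # last spoke out-only
    edges[[length(edges) + 1L]] <- tibble::tibble(
      from = in_sources, to = hub,
      sign = sample(c("+", "-"), n_s, replace = TRUE))
    edges[[length(edges) + 1L]] <- tibble::tibble(
      from = hub, to = out_targets,
      sign = sample(c("+", "-"), n_s, replace = TRUE))
  }
  de <- truth$de_genes$gene_id
  if (config$n_random_edges > 0 && length(de) >= 2) {
    hubs <- truth$hub_genes
    non_hub <- setdiff(de, hubs)
    src <- sample(non_hub, config$n_random_edges, replace = TRUE)
    dst <- sample(non_hub, config$n_random_edges, replace = TRUE)
    keep <- src != dst
    edges[[length(edges) + 1L]] <- tibble::tibble(
      from = src[keep], to = dst[keep],
      sign = sample(c("+", "-"), sum(keep), replace = TRUE))
  }
  out <- purrr::list_rbind(edges)
  if (nrow(out) == 0L) {
    return(tibble::tibble(from = character(), to = character(),
                          sign = character()))
  }
  dplyr::distinct(out, .data$from, .data$to, .keep_all = TRUE)
}

#' Simulate a pathway-pathway adjacency with a planted hub pathway
#'
#' The first enriched term is made adjacent to every other enriched term
#' (so it dominates the significant-pathway network by degree); sparse
#' random adjacency is added among the remaining terms.
#'
#' @param config A [sim_config()].
#' @param term_ids All pathway term ids (enriched first, as produced by
#'   [simulate_annotations()]).
#' @param p_background Probability of a background adjacency per pair.
#' @return Tibble of `from`, `to` pathway pairs.
#' @export
simulate_pathway_adjacency <- function(config, term_ids,
                                       p_background = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3000L)
  n_enr <- config$enriched_terms
  edges <- tibble::tibble(from = character(), to = character())
  if (n_enr >= 2) {
    edges <- tibble::tibble(from = term_ids[1], to = term_ids[2:n_enr])
  }
  others <- term_ids[-1]
  if (length(others) >= 2) {
    pairs <- t(utils::combn(others, 2))
    keep <- runif(nrow(pairs)) < p_background
    edges <- dplyr::bind_rows(
      edges, tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2]))
  }
  dplyr::distinct(edges)
}

#' Simulate a term-parent DAG
#'
#' Each term (beyond the first) gets one or two parents among
#' earlier-indexed terms, producing a random forest-like DAG for GO-map
#' construction.
#'
#' @param config A [sim_config()].
#' @param term_ids Term ids (topological order = index order).
#' @param p_second_parent Probability of a second parent.
#' @return Tibble of `child`, `parent` pairs (acyclic by construction).
#' @export
simulate_term_parents <- function(config, term_ids, p_second_parent = 0.3) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4000L)
  n <- length(term_ids)
  if (n < 2) return(tibble::tibble(child = character(), parent = character()))
  out <- purrr::map(2:n, function(i) {
    parents <- sample(i - 1L, 1L)
    if (i > 2 && runif(1) < p_second_parent) {
      parents <- unique(c(parents, sample(i - 1L, 1L)))
    }
    tibble::tibble(child = term_ids[i], parent = term_ids[parents])
  }) |> purrr::list_rbind()
  dplyr::distinct(out)
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Reference-gene Ct is constant across samples; each target's control-group
#' dCt is drawn once, and the experimental-group dCt is shifted by
#' `-log2(fold)` so that with zero noise `2^-ddCt` equals the planted fold
#' exactly.
#'
#' @param fold_changes Named vector of planted expression ratios
#'   (experimental / control).
#' @param n_replicates Samples per group.
#' @param noise_sd SD of Ct measurement noise (cycles).
#' @param reference Reference gene id.
#' @param reference_ct Reference gene Ct (cycles).
#' @param seed Integer seed.
#' @return Tibble with `gene`, `sample`, `group`, `ct`.
#' @export
simulate_ct_table <- function(fold_changes, n_replicates = 3L,
                              noise_sd = 0, reference = "Actb",
                              reference_ct = 17, seed = 1L) {
  check_count(n_replicates, "n_replicates", min = 1L)
  if (is.null(names(fold_changes)) || any(names(fold_changes) == "")) {
    abort("`fold_changes` must be a named vector.",
          class = "hubgene_config_error")
  }
  check_positive(fold_changes, "fold_changes")
  set.seed(seed)
  samples <- c(sprintf("ctrl_%d", seq_len(n_replicates)),
               sprintf("exp_%d", seq_len(n_replicates)))
  group <- rep(c("control", "experimental"), each = n_replicates)
  base_dct <- runif(length(fold_changes), 3, 8)
  rows <- purrr::imap(as.list(fold_changes), function(fc, gene) {
    i <- match(gene, names(fold_changes))
    dct <- ifelse(group == "experimental",
                  base_dct[i] - log2(fc), base_dct[i])
    tibble::tibble(gene = gene, sample = samples, group = group,
                   ct = reference_ct + dct +
                     rnorm(length(samples), 0, noise_sd))
  }) |> purrr::list_rbind()
  ref_rows <- tibble::tibble(gene = reference, sample = samples,
                             group = group, ct = reference_ct)
  dplyr::bind_rows(ref_rows, rows)
}
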
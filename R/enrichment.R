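#' Enrichment ratio Re
#'
#' `Re = (n_f / n) / (N_f / N)`: the fraction of a gene set that is
#' differential, divided by the fraction of the annotated universe that is
#' differential. Values above 1 indicate over-representation.
#'
#' @param n_f Differential genes inside the term.
#' @param n Genes in the term.
#' @param N_f Differential genes in the universe.
#' @param N Genes in the universe.
#' @return The ratio as a double.
#' @export
#' @examples
#' enrichment_ratio(10, 20, 100, 400) # 2
enrichment_ratio <- function(n_f, n, N_f, N) {
  if (any(n <= 0) || any(N_f <= 0) || any(N <= 0)) {
    abort("`n`, `N_f` and `N` must be positive.",
          class = "hubgene_domain_error")
  }
  (n_f / n) / (N_f / N)
}

check_margins <- function(n_f, n, N_f, N) {
  bad <- n_f < 0 | n_f > pmin(n, N_f) | n > N | N_f > N
  if (any(bad)) {
    abort("inconsistent 2x2 margins: need 0 <= n_f <= min(n, N_f) and n, N_f <= N.",
          class = "hubgene_domain_error")
  }
}

#' One-sided Fisher's exact test for over-representation
#'
#' Hypergeometric upper-tail probability `P(X >= n_f)` where `X` counts
#' differential genes in a random term of size `n` drawn from a universe of
#' `N` genes of which `N_f` are differential.
#'
#' @inheritParams enrichment_ratio
#' @return The one-sided p-value (vectorized).
#' @export
fisher_term_test <- function(n_f, n, N_f, N) {
  check_margins(n_f, n, N_f, N)
  phyper(n_f - 1, N_f, N - N_f, n, lower.tail = FALSE)
}

#' Pearson chi-square test on the 2x2 enrichment table
#'
#' One degree of freedom, no continuity correction. When any expected cell
#' count is below 5 the chi-square approximation is unreliable; the returned
#' tibble flags those rows (`small_cell`) so callers can fall back to
#' Fisher's exact test.
#'
#' @inheritParams enrichment_ratio
#' @return Tibble with `statistic`, `p_value`, `small_cell` (vectorized).
#' @export
chi2_term_test <- function(n_f, n, N_f, N) {
  check_margins(n_f, n, N_f, N)
  # table: rows in/out of term, cols differential yes/no
  a <- n_f; b <- n - n_f; c_ <- N_f - n_f; d <- N - n - N_f + n_f
  expected <- cbind(n * N_f / N, n * (N - N_f) / N,
                    (N - n) * N_f / N, (N - n) * (N - N_f) / N)
  observed <- cbind(a, b, c_, d)
  contrib <- ifelse(expected > 0, (observed - expected)^2 / expected, 0)
  stat <- rowSums(contrib)
  tibble::tibble(
    statistic = stat,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    small_cell = apply(expected < 5, 1, any)
  )
}

#' Over-representation analysis of a differential gene list
#'
#' Scores every term of a gene-set collection against the up-regulated list,
#' the down-regulated list, and the combined list ("both"), mirroring the
#' separate up/down function counts of a two-group screen. Selection uses
#' the one-sided Fisher p; the chi-square p is reported alongside (with the
#' small-expected-cell flag). FDR is computed within each
#' category-by-direction family.
#'
#' The universe for a category is every gene carrying at least one
#' annotation in that category; differential genes outside the universe are
#' dropped with a message.
#'
#' @param gene_sets Tibble with columns `term_id`, `name`, `category`,
#'   `gene_id` (one row per term membership), e.g. from [read_gmt()].
#' @param differential Tibble with `gene_id` and `trend` ("up"/"down"), e.g.
#'   [select_differential()] output.
#' @param p_cut,fdr_cut Strict significance cutoffs.
#' @return Tibble with one row per term x direction: counts `n_f`, `n`,
#'   `N_f`, `N`, the enrichment ratio `R_e`, `p_value` (Fisher),
#'   `chi2_p`, `chi2_small_cell`, `fdr`, `significant`.
#' @export
enrich <- function(gene_sets, differential, p_cut = 0.05, fdr_cut = 0.05) {
  stopifnot(is.data.frame(gene_sets), is.data.frame(differential))
  need <- c("term_id", "category", "gene_id")
  if (!all(need %in% names(gene_sets))) {
    abort("`gene_sets` needs columns term_id, category, gene_id.",
          class = "hubgene_domain_error")
  }
  if (nrow(gene_sets) == 0L) {
    abort("empty gene-set collection: universe undefined.",
          class = "hubgene_domain_error")
  }
  if (!"name" %in% names(gene_sets)) gene_sets$name <- gene_sets$term_id

  de_lists <- list(
    up = unique(differential$gene_id[differential$trend == "up"]),
    down = unique(differential$gene_id[differential$trend == "down"]),
    both = unique(differential$gene_id)
  )

  res <- purrr::map(unique(gene_sets$category), function(cat) {
    sets <- gene_sets[gene_sets$category == cat, ]
    universe <- unique(sets$gene_id)
    N <- length(universe)
    term_sizes <- dplyr::count(dplyr::distinct(sets, .data$term_id,
                                               .data$gene_id),
                               .data$term_id, name = "n")
    term_names <- dplyr::distinct(sets, .data$term_id, .data$name)
    purrr::map(names(de_lists), function(dir) {
      de <- de_lists[[dir]]
      outside <- setdiff(de, universe)
      if (length(outside)) {
        inform(sprintf(
          "enrich: %d differential gene(s) lack %s annotation and were dropped for that category.",
          length(outside), cat))
      }
      de <- intersect(de, universe)
      N_f <- length(de)
      hits <- sets |>
        dplyr::distinct(.data$term_id, .data$gene_id) |>
        dplyr::filter(.data$gene_id %in% de) |>
        dplyr::count(.data$term_id, name = "n_f")
      tab <- term_sizes |>
        dplyr::left_join(hits, by = "term_id") |>
        dplyr::mutate(n_f = dplyr::coalesce(.data$n_f, 0L),
                      category = cat, direction = dir,
                      N_f = N_f, N = N)
      if (N_f == 0L) {
        tab$R_e <- NA_real_
        tab$p_value <- 1
        tab$chi2_statistic <- 0
        tab$chi2_p <- 1
        tab$chi2_small_cell <- TRUE
      } else {
        tab$R_e <- enrichment_ratio(tab$n_f, tab$n, N_f, N)
        tab$p_value <- fisher_term_test(tab$n_f, tab$n, N_f, N)
        chi <- chi2_term_test(tab$n_f, tab$n, N_f, N)
        tab$chi2_statistic <- chi$statistic
        tab$chi2_p <- chi$p_value
        tab$chi2_small_cell <- chi$small_cell
      }
      tab$fdr <- bh_fdr(tab$p_value)
      tab |>
        dplyr::left_join(term_names, by = "term_id") |>
        dplyr::mutate(significant = .data$p_value < p_cut & .data$fdr < fdr_cut)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  res |>
    dplyr::select("term_id", "name", "category", "direction",
                  "n_f", "n", "N_f", "N", "R_e",
                  "p_value", "fdr", "chi2_statistic", "chi2_p",
                  "chi2_small_cell", "significant") |>
    dplyr::arrange(.data$category, .data$direction, .data$p_value,
                   .data$term_id)
}
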
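#' Relative expression by the 2^-ddCt (Livak) method
#'
#' Per sample, dCt = Ct(gene) - Ct(reference); ddCt is the mean dCt of the
#' experimental group minus the mean dCt of the control group; the relative
#' expression ratio is `2^-ddCt`. Averaging replicate dCt arithmetically is
#' equivalent to a geometric mean of the per-replicate `2^-dCt`.
#'
#' @param ct_table Tibble with columns `gene`, `sample`, `group`, `ct`.
#' @param gene Target gene id.
#' @param reference Reference (housekeeping) gene id, default `"Actb"`
#'   (beta-actin).
#' @param exp_group,ctrl_group Group labels.
#' @return One-row tibble: `gene`, `d_ct_exp`, `d_ct_ctrl`, `dd_ct`,
#'   `ratio`.
#' @export
ddct_ratio <- function(ct_table, gene, reference = "Actb",
                       exp_group = "experimental", ctrl_group = "control") {
  need <- c("gene", "sample", "group", "ct")
  if (!all(need %in% names(ct_table))) {
    abort("`ct_table` needs columns gene, sample, group, ct.",
          class = "hubgene_domain_error")
  }
  if (any(ct_table$ct <= 0 | ct_table$ct >= 45)) {
    abort("Ct values must lie in (0, 45).", class = "hubgene_domain_error")
  }
  ref <- ct_table[ct_table$gene == reference, c("sample", "ct")]
  tgt <- ct_table[ct_table$gene == gene, ]
  if (nrow(tgt) == 0L) {
    abort(sprintf("gene `%s` absent from the Ct table.", gene),
          class = "hubgene_domain_error")
  }
  no_ref <- setdiff(tgt$sample, ref$sample)
  if (length(no_ref)) {
    abort(sprintf("reference gene `%s` missing in sample(s): %s",
                  reference, paste(no_ref, collapse = ", ")),
          class = "hubgene_domain_error")
  }
  d <- tgt |>
    dplyr::inner_join(ref, by = "sample", suffix = c("", "_ref")) |>
    dplyr::mutate(d_ct = .data$ct - .data$ct_ref)
  for (g in c(exp_group, ctrl_group)) {
    if (!any(d$group == g)) {
      abort(sprintf("gene `%s` has no measurements in group `%s`.", gene, g),
            class = "hubgene_domain_error")
    }
  }
  d_exp <- mean(d$d_ct[d$group == exp_group])
  d_ctl <- mean(d$d_ct[d$group == ctrl_group])
  dd <- d_exp - d_ctl
  tibble::tibble(gene = gene, d_ct_exp = d_exp, d_ct_ctrl = d_ctl,
                 dd_ct = dd, ratio = 2^(-dd))
}

#' ddCt ratios for every target gene in a Ct table
#'
#' @inheritParams ddct_ratio
#' @return Tibble with one row per non-reference gene.
#' @export
ddct_ratios <- function(ct_table, reference = "Actb",
                        exp_group = "experimental",
                        ctrl_group = "control") {
  targets <- setdiff(unique(ct_table$gene), reference)
  purrr::map(targets, ddct_ratio, ct_table = ct_table,
             reference = reference, exp_group = exp_group,
             ctrl_group = ctrl_group) |>
    purrr::list_rbind()
}

#' Trend concordance between microarray and qPCR
#'
#' A gene agrees when its microarray fold change and its qPCR ratio fall on
#' the same side of 1 (both up or both down; a ratio of exactly 1 on both
#' platforms also agrees).
#'
#' @param microarray Tibble with `gene_id`, `fold_change`.
#' @param qpcr Tibble with `gene`, `ratio` (from [ddct_ratios()]).
#' @return Tibble per shared gene (`gene_id`, `fold_change`, `ratio`,
#'   `agree`) with the agreeing fraction as attribute `"concordance"` and
#'   in [glance()]-style summary columns via `attr`.
#' @export
concordance <- function(microarray, qpcr) {
  merged <- dplyr::inner_join(
    dplyr::select(microarray, "gene_id", "fold_change"),
    dplyr::select(qpcr, gene_id = "gene", "ratio"),
    by = "gene_id")
  merged$agree <- sign(log(merged$fold_change)) == sign(log(merged$ratio))
  attr(merged, "concordance") <-
    if (nrow(merged)) mean(merged$agree) else NA_real_
  merged
}
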
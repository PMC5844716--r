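# Plain-text readers and writers for the pipeline's file contracts.
# Every writer has a reader that restores the object losslessly.

#' Write / read an expression matrix TSV
#'
#' First column `gene_id`, one column per sample.
#'
#' @param expr Expression tibble.
#' @param path File path.
#' @return The path (writer) or the tibble (reader).
#' @export
write_expression_tsv <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(gene_id = "c", .default = "d"))
}

#' Write / read the sample-group mapping TSV
#'
#' Columns `sample_id`, `group`.
#'
#' @param groups Groups tibble.
#' @param path File path.
#' @export
write_groups_tsv <- function(groups, path) {
  readr::write_tsv(groups, path)
  invisible(path)
}

#' @rdname write_groups_tsv
#' @export
read_groups_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' Write / read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated
#' `term_id <TAB> description <TAB> member1 <TAB> member2 ...`. The
#' category is not part of the format; supply it when reading.
#'
#' @param gene_sets Tibble with `term_id`, `name`, `gene_id` (and
#'   optionally `category`).
#' @param path File path.
#' @param category Category label attached on read (default "GO").
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- gene_sets |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(
      line = paste(c(.data$term_id[1],
                     if ("name" %in% names(gene_sets)) .data$name[1]
                     else .data$term_id[1],
                     sort(.data$gene_id)),
                   collapse = "\t"),
      .groups = "drop") |>
    dplyr::arrange(.data$term_id)
  writeLines(lines$line, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, category = "GO") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  purrr::map(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      abort(sprintf("malformed GMT line: %s", substr(line, 1, 40)),
            class = "hubgene_domain_error")
    }
    tibble::tibble(term_id = parts[1], name = parts[2],
                   category = category, gene_id = parts[-(1:2)])
  }) |> purrr::list_rbind()
}

#' Write / read an interaction edge TSV
#'
#' Columns `from`, `to`, `sign` (+/-).
#'
#' @param edges Edge tibble.
#' @param path File path.
#' @export
write_interaction_tsv <- function(edges, path) {
  readr::write_tsv(edges, path)
  invisible(path)
}

#' @rdname write_interaction_tsv
#' @export
read_interaction_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' Write / read a two-column pair TSV (pathway adjacency, term parents)
#'
#' @param pairs Tibble with two character columns.
#' @param path File path.
#' @export
write_pairs_tsv <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}

#' @rdname write_pairs_tsv
#' @export
read_pairs_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' Write / read a qPCR Ct CSV
#'
#' Columns `gene`, `sample`, `group`, `ct`.
#'
#' @param ct_table Ct tibble.
#' @param path File path.
#' @export
write_ct_csv <- function(ct_table, path) {
  readr::write_csv(ct_table, path)
  invisible(path)
}

#' @rdname write_ct_csv
#' @export
read_ct_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(ct = "d", .default = "c"))
}

#' Write / read simulation ground truth as JSON
#'
#' @param truth Ground-truth list from [simulate_expression()] (optionally
#'   extended with `enriched_term_ids`).
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$de_genes <- tibble::as_tibble(raw$de_genes)
  if (!is.null(raw$hub_blocks)) raw$hub_blocks <- as.list(raw$hub_blocks)
  raw
}

#' Write a differential-results TSV in printed-table column order
#'
#' Column order gene, p, FDR, geometric means, fold change, trend; fold
#' change rounded to 2 decimals and p/FDR in scientific notation for the
#' report file (internal tibbles keep full precision).
#'
#' @param records [diff_expression()] output.
#' @param path File path.
#' @export
write_differential_tsv <- function(records, path) {
  out <- records |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      p_value = formatC(.data$p_value, format = "e", digits = 3),
      fdr = formatC(.data$fdr, format = "e", digits = 3),
      geom_mean_exp = round(.data$geom_mean_exp, 2),
      geom_mean_ctrl = round(.data$geom_mean_ctrl, 2),
      fold_change = round(.data$fold_change, 2),
      trend = .data$trend
    )
  readr::write_tsv(out, path)
  invisible(path)
}
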
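#' Packaged example tables
#'
#' `top_differential_table()` returns a published-style top-20 differential
#' gene table (gene symbol, p, FDR, per-group geometric mean intensities,
#' fold change, trend) from a 3 vs 3 mouse brain hypoxia-preconditioning
#' microarray; the intensity pairs serve as worked fold-change examples.
#' Gene symbols may repeat (distinct probes for the same symbol).
#' `qpcr_primer_table()` returns the matching RT-PCR primer table.
#'
#' @return A tibble.
#' @export
top_differential_table <- function() {
  readr::read_tsv(
    system.file("extdata", "top20_differential_genes.tsv",
                package = "hubgene", mustWork = TRUE),
    show_col_types = FALSE,
    col_types = readr::cols(gene_symbol = "c", trend = "c", .default = "d"))
}

#' @rdname top_differential_table
#' @export
qpcr_primer_table <- function() {
  readr::read_tsv(
    system.file("extdata", "qpcr_primers.tsv",
                package = "hubgene", mustWork = TRUE),
    show_col_types = FALSE,
    col_types = readr::cols(product_length = "i", .default = "c"))
}
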
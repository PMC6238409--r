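#' Published miTRAP interaction roster for the mouse Pax6 3'UTR
#'
#' The per-category roster of the 40 alpha-cell-expressed miRNAs assayed
#' by miTRAP against the Pax6 3'UTR, transcribed from the published
#' summary table: 17 high-confidence interactors, 8 low-confidence,
#' 1 non-specific and 14 undetected, with each miRNA's strongest MRE
#' type. Feed it to [classification_summary()] to recompute the published
#' category percentages.
#'
#' @return Tibble `mirna, mre_type, category`.
#' @export
#' @examples
#' classification_summary(mitrap_table1())
mitrap_table1 <- function() {
  path <- system.file("extdata", "mitrap_table1_categories.tsv",
                      package = "seedscape", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}
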
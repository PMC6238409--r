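#' Run the full 3'UTR miRNA-landscape pipeline
#'
#' Orchestrates scan -> funnel -> quantify -> classify -> landscape from a
#' single configuration. The configuration can be a YAML file path or a
#' nested list with elements:
#' \describe{
#'   \item{utr}{UTR sequence string, or `utr_fasta` path.}
#'   \item{mirnas}{miRNA tibble, or `mirna_fasta` path.}
#'   \item{alignment}{An [ortholog_alignment()], or `alignment_fasta` path
#'     plus `reference` (optional; the conservation stage needs either
#'     this or sites carrying a `conservation` column).}
#'   \item{plates}{Ct tibble, or `plate_file` path (optional; when absent
#'     or empty, quantification and landscape are skipped with a warning).}
#'   \item{scan, filter, qpcr, landscape}{Argument lists forwarded to
#'     [seed_match_config()], [filter_config()], [qpcr_config()],
#'     [landscape_config()].}
#'   \item{out_dir}{Optional directory for TSV/BED outputs.}
#' }
#'
#' @param config Nested list or YAML file path.
#' @return An object of class `pipeline_report`: `sites` (scanned
#'   universe), `funnel` (survivors + `funnel_report`), `classification`
#'   (per-miRNA categories), `summary` (category counts/percentages),
#'   `landscape` (a `utr_landscape` or `NULL`), `clusters`,
#'   `cooperative_pairs`, `qc_discarded`, `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg_scan <- do.call(seed_match_config, config$scan %||% list())
  cfg_filter <- do.call(filter_config, config$filter %||% list())
  cfg_qpcr <- do.call(qpcr_config, config$qpcr %||% list())
  cfg_land <- do.call(landscape_config, config$landscape %||% list())

  utr <- config$utr %||%
    (if (!is.null(config$utr_fasta)) read_utr_fasta(config$utr_fasta))
  if (is.null(utr)) abort("pipeline config needs a utr or utr_fasta")
  mirnas <- config$mirnas %||%
    (if (!is.null(config$mirna_fasta)) read_mirna_fasta(config$mirna_fasta))
  if (is.null(mirnas)) abort("pipeline config needs mirnas or mirna_fasta")
  aln <- config$alignment %||%
    (if (!is.null(config$alignment_fasta)) {
      read_ortholog_alignment(config$alignment_fasta, config$reference)
    })
  plates <- config$plates %||%
    (if (!is.null(config$plate_file)) read_plate_table(config$plate_file))

  inform("scan: enumerating MRE sites")
  sites <- scan_mres(utr, mirnas, cfg_scan)

  inform("filter: applying the candidate funnel")
  funnel <- apply_funnel(sites, mirnas = mirnas, aln = aln,
                         config = cfg_filter,
                         reference_counts = config$reference_counts)

  classification <- NULL
  summary_tbl <- NULL
  land <- NULL
  clusters <- NULL
  pairs <- NULL
  qc_discarded <- NULL
  if (is.null(plates) || nrow(plates) == 0L) {
    warn("no plate records supplied; quantification and landscape skipped")
  } else {
    inform("quantify: QC, NRQ and interaction classification")
    qc <- qc_filter(plates, cfg_qpcr)
    qc_discarded <- qc$discarded
    classification <- mitrap_classify(plates, cfg_qpcr)
    summary_tbl <- classification_summary(classification)
    interactors <- filter(classification,
                          .data$category %in%
                            c("high_confidence", "low_confidence"))
    site_nrq <- funnel$sites %>%
      filter(.data$mirna %in% interactors$mirna) %>%
      left_join(select(interactors, "mirna", "nrq"), by = "mirna")
    if (nrow(site_nrq) > 0L) {
      inform("landscape: positional track, pairs and clusters")
      land <- build_landscape(
        tibble(mirna = site_nrq$mirna, position = site_nrq$start,
               nrq = site_nrq$nrq),
        utr_length = nchar(normalize_seq(utr)), config = cfg_land
      )
      clusters <- cluster_regions(land, cfg_land)
      pairs <- cooperative_pairs(
        tibble(mirna = site_nrq$mirna, position = site_nrq$start,
               start = site_nrq$start, end = site_nrq$end),
        cfg_land
      )
    }
  }

  report <- structure(
    list(
      sites = sites, funnel = funnel, classification = classification,
      summary = summary_tbl, landscape = land, clusters = clusters,
      cooperative_pairs = pairs, qc_discarded = qc_discarded,
      config = list(scan = cfg_scan, filter = cfg_filter, qpcr = cfg_qpcr,
                    landscape = cfg_land)
    ),
    class = "pipeline_report"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(sites, file.path(config$out_dir, "sites.tsv"))
    readr::write_tsv(funnel$report$stages,
                     file.path(config$out_dir, "funnel_stages.tsv"))
    if (!is.null(classification)) {
      readr::write_tsv(classification,
                       file.path(config$out_dir, "classification.tsv"))
    }
    if (!is.null(land)) {
      write_bedgraph(land$track, file.path(config$out_dir, "landscape.bedgraph"))
      write_bed6(land$peaks %>% mutate(name = .data$mirna,
                                       score = .data$height),
                 file.path(config$out_dir, "peaks.bed"))
    }
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  sites scanned: %d\n", nrow(x$sites)))
  print(x$funnel$report)
  if (!is.null(x$summary)) {
    cat("  interaction classification:\n")
    print(x$summary)
  }
  if (!is.null(x$landscape)) print(x$landscape)
  invisible(x)
}
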
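#' Per-replicate Pfaffl NRQs from a QC-passed plate table
#'
#' Pairs test and control pull-down replicates by replicate index and
#' forms, for every miRNA assay, the delta-Ct contrasts
#' `dCt = Ct(control) - Ct(test)` for the miRNA and for the bait, then
#' the Pfaffl NRQ `e_taqman^dCt_miRNA / e_bait^dCt_bait`. Undetermined
#' Cts propagate as `NA` NRQs.
#'
#' @param records Plus-RT Ct tibble (e.g. the `kept` element of
#'   [qc_filter()]).
#' @param config A [qpcr_config()].
#' @param test_condition,control_condition Condition labels of the test
#'   (UTR bait) and control pull-downs.
#' @param bait_assay Assay name of the bait transcript (default `"GFP"`).
#' @return Tibble `mirna, replicate, nrq`.
#' @export
replicate_nrqs <- function(records, config = qpcr_config(),
                           test_condition = "wt_utr",
                           control_condition = "control_utr",
                           bait_assay = "GFP") {
  pull <- filter(records, .data$condition %in%
                   c(test_condition, control_condition))
  wide <- pull %>%
    select("assay", "condition", "replicate", "ct") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "ct")
  if (!all(c(test_condition, control_condition) %in% names(wide))) {
    abort("both pull-down conditions must be present in the records")
  }
  bait <- filter(wide, .data$assay == bait_assay)
  if (nrow(bait) == 0L) {
    abort(sprintf("bait assay '%s' not found", bait_assay))
  }
  bait$dct_bait <- bait[[control_condition]] - bait[[test_condition]]
  mirnas <- filter(wide, .data$assay != bait_assay)
  mirnas$dct_mirna <- mirnas[[control_condition]] - mirnas[[test_condition]]
  out <- left_join(
    select(mirnas, mirna = "assay", "replicate", "dct_mirna"),
    select(bait, "replicate", "dct_bait"),
    by = "replicate"
  )
  out$nrq <- pfaffl_nrq(out$dct_mirna, out$dct_bait, config)
  select(out, "mirna", "replicate", "nrq") %>%
    arrange(.data$mirna, .data$replicate)
}

#' Classify every assayed miRNA from a raw plate table
#'
#' Runs [qc_filter()], computes per-replicate NRQs with
#' [replicate_nrqs()], and classifies each miRNA with
#' [classify_interaction()]. Detection requires Ct below the detection
#' threshold in every test pull-down replicate.
#'
#' @inheritParams replicate_nrqs
#' @param records Raw Ct tibble including any minus-RT wells.
#' @return Tibble `mirna, nrq, ci_low, ci_high, detected, category`.
#' @export
mitrap_classify <- function(records, config = qpcr_config(),
                            test_condition = "wt_utr",
                            control_condition = "control_utr",
                            bait_assay = "GFP") {
  qc <- qc_filter(records, config, test_condition = test_condition,
                  control_condition = control_condition)
  kept <- qc$kept
  detected_tbl <- kept %>%
    filter(.data$condition == test_condition, .data$assay != bait_assay) %>%
    group_by(.data$assay) %>%
    summarise(detected = all(!is.na(.data$ct) &
                               .data$ct < config$detect_ct_max),
              .groups = "drop")
  nrqs <- replicate_nrqs(kept, config, test_condition, control_condition,
                         bait_assay)
  out <- lapply(detected_tbl$assay, function(a) {
    det <- detected_tbl$detected[detected_tbl$assay == a]
    reps <- nrqs$nrq[nrqs$mirna == a]
    cls <- if (!det) {
      classify_interaction(numeric(), detected = FALSE, config = config)
    } else {
      classify_interaction(reps[!is.na(reps)], detected = TRUE,
                           config = config)
    }
    cls$mirna <- a
    cls
  })
  bind_rows(out) %>%
    select("mirna", "nrq", "ci_low", "ci_high", "detected", "category") %>%
    arrange(.data$mirna)
}
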
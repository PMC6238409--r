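#' qPCR quantification configuration
#'
#' Defaults mirror a SYBR-green bait assay with measured efficiency 1.952
#' and TaqMan miRNA assays assumed to double per cycle.
#'
#' @param e_bait Bait (GFP) primer efficiency, fold amplification per cycle.
#' @param e_taqman miRNA-assay efficiency.
#' @param detect_ct_max Detection threshold: a target counts as detected
#'   only when Ct is below this in all required replicates (default 40).
#' @param no_rt_margin Minimum Ct(no-RT) - Ct(+RT) margin; samples below it
#'   are excluded (default 10).
#' @param replicate_sd_max Maximum technical-replicate Ct standard
#'   deviation (default 0.5).
#' @param undefined_ct_substitute Ct substituted for undetermined
#'   control-pulldown wells when the target is detected in all test
#'   pulldowns (default 40).
#' @param pulldown_replicates Independent pull-down replicates (default 4).
#' @param profiling_replicates Profiling replicates (default 3).
#' @param nonspecific_nrq_max NRQ at or below which a detected interaction
#'   is called non-specific (default 1).
#' @return A list of class `qpcr_config`.
#' @export
qpcr_config <- function(e_bait = 1.952, e_taqman = 2,
                        detect_ct_max = 40, no_rt_margin = 10,
                        replicate_sd_max = 0.5,
                        undefined_ct_substitute = 40,
                        pulldown_replicates = 4L,
                        profiling_replicates = 3L,
                        nonspecific_nrq_max = 1) {
  for (e in c(e_bait, e_taqman)) {
    if (e <= 1 || e > 2) abort("efficiencies must satisfy 1 < e <= 2")
  }
  structure(
    list(
      e_bait = e_bait, e_taqman = e_taqman,
      detect_ct_max = detect_ct_max, no_rt_margin = no_rt_margin,
      replicate_sd_max = replicate_sd_max,
      undefined_ct_substitute = undefined_ct_substitute,
      pulldown_replicates = as.integer(pulldown_replicates),
      profiling_replicates = as.integer(profiling_replicates),
      nonspecific_nrq_max = nonspecific_nrq_max
    ),
    class = "qpcr_config"
  )
}

#' Estimate amplification efficiency from a dilution standard curve
#'
#' Fits Ct against log10(fold dilution) by least squares and returns
#' efficiency `10^(1/slope)` (fold amplification per cycle; 2 = perfect
#' doubling). A warning (not an error) is raised when the fit's r-squared
#' falls below `r2_min`.
#'
#' @param series Tibble with columns `fold_dilution` (strictly increasing,
#'   e.g. `10^(0:4)` for a ten-fold series) and `ct`.
#' @param r2_min Minimum acceptable squared correlation (default 0.99).
#' @return An object of class `standard_curve` with elements `efficiency`,
#'   `slope`, `intercept`, `r2`, `n`, `fit`.
#' @export
#' @examples
#' s <- tibble::tibble(fold_dilution = 10^(0:4), ct = 20 + 3.4426 * (0:4))
#' estimate_efficiency(s)$efficiency # 1.952
estimate_efficiency <- function(series, r2_min = 0.99) {
  if (!all(c("fold_dilution", "ct") %in% names(series))) {
    abort("series must have columns fold_dilution and ct")
  }
  if (nrow(series) < 3L) abort("a standard curve needs at least 3 points")
  if (any(diff(series$fold_dilution) <= 0)) {
    abort("fold dilutions must be strictly increasing")
  }
  fit <- lm(ct ~ log10(fold_dilution), data = series)
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || slope == 0) abort("standard curve slope is zero")
  r2 <- suppressWarnings(summary(fit)$r.squared) # noiseless curves fit exactly
  if (r2 < r2_min) {
    warn(sprintf("standard curve r-squared %.4f is below %.2f", r2, r2_min))
  }
  structure(
    list(
      efficiency = 10^(1 / slope), slope = slope,
      intercept = unname(coef(fit)[1L]), r2 = r2,
      n = nrow(series), fit = fit
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> efficiency %.3f (slope %.4f cycles/decade, r2 %.4f, n = %d)\n",
    x$efficiency, x$slope, x$r2, x$n
  ))
  invisible(x)
}

#' @rdname estimate_efficiency
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.standard_curve <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname estimate_efficiency
#' @exportS3Method generics::glance
glance.standard_curve <- function(x, ...) {
  tibble(efficiency = x$efficiency, slope = x$slope, r.squared = x$r2,
         n = x$n)
}

#' Quality-control filter for qPCR Ct records
#'
#' Applies, in order: (a) exclusion of `(sample, assay)` pairs whose
#' no-RT margin `Ct(no-RT) - Ct(+RT)` is below `no_rt_margin` (an
#' undetermined no-RT well passes); (b) discard of technical-replicate
#' groups whose Ct standard deviation exceeds `replicate_sd_max`;
#' (c) detection flagging: an assay is `detected` in a condition only when
#' Ct is below `detect_ct_max` in every replicate; (d) for control
#' conditions only, substitution of undetermined Ct with
#' `undefined_ct_substitute` when the assay is detected in every test
#' (pull-down) replicate. Every discarded well carries its rule tag.
#'
#' @param records Ct tibble (`sample, assay, condition, replicate, ct,
#'   rt_control`); `ct = NA` encodes an undetermined well.
#' @param config A [qpcr_config()].
#' @param test_condition Condition holding the test pull-downs
#'   (default `"wt_utr"`).
#' @param control_condition Condition receiving the undetermined-Ct
#'   substitution (default `"control_utr"`).
#' @param missing_rt Behaviour when a well has no minus-RT partner:
#'   `"warn"` skips rule (a) for it with a warning, `"error"` aborts.
#' @return A list of class `qc_result`: `kept` (plus-RT wells surviving
#'   QC, with `detected` and `ct_substituted` columns) and `discarded`
#'   (with a `reason` column among `no_rt_margin`, `replicate_sd`).
#' @export
qc_filter <- function(records, config = qpcr_config(),
                      test_condition = "wt_utr",
                      control_condition = "control_utr",
                      missing_rt = c("warn", "error")) {
  missing_rt <- match.arg(missing_rt)
  discarded <- records[0, ]
  discarded$reason <- character()

  minus <- filter(records, .data$rt_control)
  plus <- filter(records, !.data$rt_control)

  # (a) no-RT margin, resolved per (sample, assay)
  if (nrow(minus) > 0L) {
    margins <- minus %>%
      group_by(.data$sample, .data$assay) %>%
      summarise(ct_no_rt = min(.data$ct, na.rm = FALSE), .groups = "drop")
    plus <- left_join(plus, margins, by = c("sample", "assay"))
    # undetermined no-RT (NA) = no amplification without RT: margin passes
    fail <- !is.na(plus$ct_no_rt) & !is.na(plus$ct) &
      (plus$ct_no_rt - plus$ct) < config$no_rt_margin
    if (any(fail)) {
      d <- plus[fail, names(records)]
      d$reason <- "no_rt_margin"
      discarded <- bind_rows(discarded, d)
      plus <- plus[!fail, , drop = FALSE]
    }
    plus$ct_no_rt <- NULL
  } else if (nrow(plus) > 0L) {
    if (missing_rt == "error") abort("no minus-RT control wells present")
    warn("no minus-RT control wells present; no-RT margin rule skipped")
  }

  # (b) technical-replicate scatter
  if (nrow(plus) > 0L) {
    plus <- plus %>%
      group_by(.data$sample, .data$assay, .data$condition) %>%
      mutate(.rep_sd = if (sum(!is.na(.data$ct)) >= 2L) {
        sd(.data$ct, na.rm = TRUE)
      } else 0) %>%
      ungroup()
    fail <- plus$.rep_sd > config$replicate_sd_max
    if (any(fail)) {
      d <- plus[fail, names(records)]
      d$reason <- "replicate_sd"
      discarded <- bind_rows(discarded, d)
      plus <- plus[!fail, , drop = FALSE]
    }
    plus$.rep_sd <- NULL
  }

  # (c) detection: Ct < max in all replicates of the condition
  if (nrow(plus) > 0L) {
    plus <- plus %>%
      group_by(.data$assay, .data$condition) %>%
      mutate(detected = all(!is.na(.data$ct) &
                              .data$ct < config$detect_ct_max)) %>%
      ungroup()
  } else {
    plus$detected <- logical()
  }

  # (d) undetermined-Ct substitution in the control condition
  plus$ct_substituted <- FALSE
  if (nrow(plus) > 0L) {
    detected_in_test <- plus %>%
      filter(.data$condition == test_condition) %>%
      group_by(.data$assay) %>%
      summarise(ok = all(!is.na(.data$ct) &
                           .data$ct < config$detect_ct_max),
                .groups = "drop")
    sub <- plus$condition == control_condition & is.na(plus$ct) &
      plus$assay %in% detected_in_test$assay[detected_in_test$ok]
    plus$ct[sub] <- config$undefined_ct_substitute
    plus$ct_substituted[sub] <- TRUE
  }

  structure(list(kept = plus, discarded = discarded), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %d wells kept, %d discarded\n",
              nrow(x$kept), nrow(x$discarded)))
  if (nrow(x$discarded) > 0L) print(count(x$discarded, .data$reason))
  invisible(x)
}

#' Expression relative to a reference assay (delta-Ct method)
#'
#' `2^(ct_reference - ct_target)`, e.g. a miRNA level relative to U6.
#' Undetermined input propagates as `NA`, never as zero.
#'
#' @param ct_target Target Ct (vectorized).
#' @param ct_reference Reference (e.g. U6) Ct.
#' @return A tibble with `ratio` and `percent_of_reference`.
#' @export
relative_expression <- function(ct_target, ct_reference) {
  ratio <- 2^(ct_reference - ct_target)
  tibble(ratio = ratio, percent_of_reference = 100 * ratio)
}

#' Efficiency-corrected fold difference between two conditions
#'
#' `e^(ct_reference_condition - ct_test_condition)`.
#'
#' @param e Assay efficiency (fold amplification per cycle, in (1, 2]).
#' @param ct_ref_condition Ct in the reference condition.
#' @param ct_test_condition Ct in the test condition.
#' @return Fold-difference ratio (vectorized).
#' @export
fold_difference <- function(e, ct_ref_condition, ct_test_condition) {
  if (any(e <= 1)) abort("efficiency must exceed 1")
  e^(ct_ref_condition - ct_test_condition)
}

#' Pfaffl efficiency-corrected normalized relative quantity
#'
#' `e_taqman^dct_mirna / e_bait^dct_bait`, with delta-Ct contrasts formed
#' by the caller (e.g. control-pulldown Ct minus test-pulldown Ct).
#' Undefined delta-Ct propagates as `NA`.
#'
#' @param dct_mirna miRNA delta-Ct.
#' @param dct_bait Bait (GFP) delta-Ct.
#' @param config A [qpcr_config()] supplying the efficiencies.
#' @return NRQ (vectorized).
#' @export
pfaffl_nrq <- function(dct_mirna, dct_bait, config = qpcr_config()) {
  config$e_taqman^dct_mirna / config$e_bait^dct_bait
}

#' miTRAP enrichment ratio
#'
#' Pull-down relative miRNA abundance
#' `e_bait^mean_ct_bait / e_taqman^mean_ct_mirna` divided by the lysate
#' relative abundance (from [relative_expression()]), measuring
#' UTR-specific enrichment independent of cellular expression level.
#'
#' @param mean_ct_bait Mean bait (GFP) Ct over the pull-down replicates.
#' @param mean_ct_mirna Mean miRNA Ct over the pull-down replicates.
#' @param rel_abundance_lysate Lysate miRNA abundance relative to the
#'   reference assay (must be positive).
#' @param config A [qpcr_config()].
#' @return miTRAP ratio (vectorized).
#' @export
mitrap_ratio <- function(mean_ct_bait, mean_ct_mirna, rel_abundance_lysate,
                         config = qpcr_config()) {
  if (any(!is.na(rel_abundance_lysate) & rel_abundance_lysate <= 0)) {
    abort("lysate relative abundance must be positive")
  }
  (config$e_bait^mean_ct_bait / config$e_taqman^mean_ct_mirna) /
    rel_abundance_lysate
}

#' Classify a miTRAP interaction from per-replicate NRQs
#'
#' The point NRQ is the geometric mean of the replicate NRQs; the 95%
#' confidence interval is a t interval on log2 NRQs, back-transformed.
#' Categories: `no_interaction` when the target is not detected in every
#' test pull-down; `non_specific` when detected with point NRQ at or below
#' `nonspecific_nrq_max`; `low_confidence` when NRQ exceeds 1 but the CI
#' lower bound does not; `high_confidence` when both do.
#'
#' @param nrq_replicates Numeric vector of per-replicate NRQs.
#' @param detected Logical: detected in all test pull-down replicates.
#' @param config A [qpcr_config()] (`pulldown_replicates` sets the
#'   required replicate count).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `nrq`, `ci_low`, `ci_high`, `detected`,
#'   `category`.
#' @export
classify_interaction <- function(nrq_replicates, detected = TRUE,
                                 config = qpcr_config(),
                                 conf_level = 0.95) {
  if (!isTRUE(detected)) {
    return(tibble(nrq = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  detected = FALSE, category = "no_interaction"))
  }
  n <- length(nrq_replicates)
  if (n < config$pulldown_replicates) {
    abort(sprintf("need %d replicate NRQs, got %d",
                  config$pulldown_replicates, n))
  }
  if (any(is.na(nrq_replicates)) || any(nrq_replicates <= 0)) {
    abort("replicate NRQs must be positive and defined")
  }
  lg <- log2(nrq_replicates)
  m <- mean(lg)
  half <- if (n > 1L && sd(lg) > 0) {
    qt(1 - (1 - conf_level) / 2, df = n - 1L) * sd(lg) / sqrt(n)
  } else 0
  nrq <- 2^m
  ci_low <- 2^(m - half)
  ci_high <- 2^(m + half)
  category <- if (nrq <= config$nonspecific_nrq_max) {
    "non_specific"
  } else if (ci_low > 1) {
    "high_confidence"
  } else {
    "low_confidence"
  }
  tibble(nrq = nrq, ci_low = ci_low, ci_high = ci_high, detected = TRUE,
         category = category)
}

#' Summarize interaction categories as counts and percentages
#'
#' All four categories are always reported (zero counts included);
#' percentages are over all classified targets and sum to 100. The
#' combined interaction percentage (high plus low confidence) is attached
#' as a column.
#'
#' @param classified Tibble with a `category` column (one row per target).
#' @return Tibble `category, n, percent, interaction_percent`.
#' @export
classification_summary <- function(classified) {
  levels <- c("high_confidence", "low_confidence", "non_specific",
              "no_interaction")
  bad <- setdiff(unique(classified$category), levels)
  if (length(bad) > 0L) {
    abort(paste("unknown categories:", paste(bad, collapse = ", ")))
  }
  n_total <- nrow(classified)
  counts <- table(factor(classified$category, levels = levels))
  out <- tibble(
    category = levels,
    n = as.integer(counts),
    percent = if (n_total > 0L) 100 * as.integer(counts) / n_total else
      rep(NA_real_, 4L)
  )
  out$interaction_percent <- if (n_total > 0L) {
    sum(out$percent[out$category %in% c("high_confidence", "low_confidence")])
  } else NA_real_
  out
}
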
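test_that("standard-curve efficiency follows 10^(1/slope)", {
  s <- tibble::tibble(fold_dilution = 10^(0:4), ct = 21.3 + 3.4426 * (0:4))
  fit <- estimate_efficiency(s)
  expect_equal(round(fit$efficiency, 3), 1.952)
  # perfect doubling: 1/log10(2) cycles per decade
  s2 <- tibble::tibble(fold_dilution = 10^(0:4), ct = 18 + (0:4) / log10(2))
  expect_equal(estimate_efficiency(s2)$efficiency, 2, tolerance = 1e-10)
  # generator round-trip at arbitrary efficiency
  for (e in c(1.7, 1.85, 1.952, 2)) {
    series <- gen_dilution_series(e, n_points = 6, c0 = 19, rng_seed = 1)
    expect_equal(estimate_efficiency(series)$efficiency, e, tolerance = 1e-12)
  }
  expect_error(estimate_efficiency(s[1:2, ]), "3 points")
  expect_warning(
    estimate_efficiency(tibble::tibble(fold_dilution = 10^(0:3),
                                       ct = c(20, 27, 26, 33))),
    "r-squared"
  )
})

test_that("delta-Ct expression, fold difference, Pfaffl NRQ and miTRAP ratio arithmetic", {
  expect_equal(relative_expression(25, 25)$ratio, 1)
  re <- relative_expression(30, 20)
  expect_equal(re$ratio, 2^-10)
  expect_equal(re$percent_of_reference, 100 * 2^-10)
  # the ~0.01%-of-reference bracket corresponds to dCt ~ -13.29
  expect_equal(relative_expression(20 + 13.29, 20)$percent_of_reference,
               0.01, tolerance = 0.01)
  expect_true(is.na(relative_expression(NA, 20)$ratio))

  expect_equal(fold_difference(1.7, 25, 25), 1)
  expect_equal(fold_difference(1.952, 30, 25), 1.952^5)
  expect_equal(fold_difference(2, 22.32, 20), 2^2.32)
  expect_equal(2^2.32, 4.993, tolerance = 1e-3)
  expect_error(fold_difference(0.9, 20, 20), "exceed 1")

  expect_equal(pfaffl_nrq(0, 0), 1)
  expect_equal(pfaffl_nrq(3, 1), 8 / 1.952)
  expect_true(is.na(pfaffl_nrq(NA, 1)))
  # with equal efficiencies of 2 the Pfaffl ratio reduces to 2^ddCt
  cfg2 <- qpcr_config(e_bait = 2, e_taqman = 2)
  expect_equal(pfaffl_nrq(3.7, 1.2, cfg2), 2^(3.7 - 1.2))

  expect_equal(mitrap_ratio(20, 25, (1.952^20 / 2^25)), 1)
  expect_equal(mitrap_ratio(20, 25, 0.01), (1.952^20 / 2^25) / 0.01)
  # one extra miRNA cycle halves the pulldown abundance, and the ratio
  expect_equal(mitrap_ratio(20, 26, 0.01), mitrap_ratio(20, 25, 0.01) / 2)
  expect_error(mitrap_ratio(20, 25, 0), "positive")
})

test_that("QC rules fire in order with tagged discards and the control-Ct substitution", {
  cfg <- qpcr_config()
  rec <- tibble::tibble(
    sample = c("s1", "s1", "s2", "s2", "s2", "s2"),
    assay = c("miR-x", "miR-x", "miR-y", "miR-y", "miR-y", "miR-y"),
    condition = "wt_utr",
    replicate = c(1L, 1L, 1L, 2L, 3L, 1L),
    ct = c(30, 38, 25.0, 25.4, 26.2, NA),
    rt_control = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE)
  )
  qc <- qc_filter(rec, cfg)
  # s1: margin 38 - 30 = 8 < 10 -> excluded
  expect_true(all(qc$discarded$reason[qc$discarded$sample == "s1"] == "no_rt_margin"))
  # s2 triplicate sd ~0.61 > 0.5 -> discarded; independently recomputed
  expect_gt(sd(c(25.0, 25.4, 26.2)), 0.5)
  expect_setequal(qc$discarded$reason[qc$discarded$sample == "s2"], "replicate_sd")
  expect_equal(nrow(qc$kept), 0L)

  # undetermined control Ct substitution when detected in all 4 test pulldowns
  rec2 <- tibble::tibble(
    sample = paste0("p", c(1:4, 1:4)),
    assay = "miR-z",
    condition = rep(c("wt_utr", "control_utr"), each = 4L),
    replicate = rep(1:4, 2L),
    ct = c(28, 28.2, 27.9, 28.1, 33, 33.4, NA, 33.2),
    rt_control = FALSE
  )
  qc2 <- suppressWarnings(qc_filter(rec2, cfg))
  subbed <- qc2$kept[qc2$kept$condition == "control_utr" & qc2$kept$replicate == 3L, ]
  expect_equal(subbed$ct, 40)
  expect_true(subbed$ct_substituted)
  # without full test-side detection the substitution must not happen
  rec3 <- rec2
  rec3$ct[2] <- NA
  qc3 <- suppressWarnings(qc_filter(rec3, cfg))
  expect_true(is.na(qc3$kept$ct[qc3$kept$condition == "control_utr" &
                                  qc3$kept$replicate == 3L]))
  # idempotence: re-filtering kept wells discards nothing new
  again <- suppressWarnings(qc_filter(qc2$kept[, names(rec2)], cfg))
  expect_equal(nrow(again$discarded), 0L)
  expect_equal(again$kept$ct, qc2$kept$ct)
})

test_that("minus-RT wells 12 cycles above +RT pass the margin-10 rule", {
  spec <- ct_sim_spec("miR-a", enrichment = 4, no_rt_offset = 12)
  plate <- gen_ct_experiment(spec, rng_seed = 2)
  qc <- qc_filter(plate)
  expect_equal(nrow(qc$discarded), 0L)
})

test_that("interaction classification applies the NRQ/CI category rules", {
  cfg <- qpcr_config()
  hi <- classify_interaction(c(8, 12, 20, 30), TRUE, cfg)
  expect_equal(hi$category, "high_confidence")
  expect_true(hi$ci_low > 1 && hi$ci_low <= hi$nrq && hi$nrq <= hi$ci_high)
  # point NRQ is the geometric mean
  expect_equal(hi$nrq, exp(mean(log(c(8, 12, 20, 30)))))
  lo <- classify_interaction(c(0.4, 1.2, 3.1, 4.6), TRUE, cfg)
  expect_equal(lo$category, "low_confidence")
  expect_true(lo$nrq > 1 && lo$ci_low <= 1)
  ns <- classify_interaction(c(0.8, 1.1, 0.9, 1.05), TRUE, cfg)
  expect_equal(ns$category, "non_specific")
  nd <- classify_interaction(numeric(), FALSE, cfg)
  expect_equal(nd$category, "no_interaction")
  expect_error(classify_interaction(c(2, 3, 4), TRUE, cfg), "replicate")
})

test_that("classification summary always reports four categories summing to 100%", {
  tbl <- tibble::tibble(category = c(rep("high_confidence", 3),
                                     rep("no_interaction", 1)))
  s <- classification_summary(tbl)
  expect_equal(nrow(s), 4L)
  expect_equal(sum(s$percent), 100)
  expect_equal(s$percent[s$category == "high_confidence"], 75)
  expect_equal(unique(s$interaction_percent), 75)
  expect_error(classification_summary(tibble::tibble(category = "maybe")),
               "unknown")
})

test_that("noiseless synthetic experiments invert to the configured enrichment exactly", {
  spec <- ct_sim_spec(c("m1", "m2", "m3"), enrichment = c(8, 2, 1),
                      noise_sd = 0)
  plate <- gen_ct_experiment(spec, rng_seed = 10)
  cls <- mitrap_classify(plate)
  expect_equal(cls$nrq[match(c("m1", "m2", "m3"), cls$mirna)], c(8, 2, 1))
  expect_equal(cls$category[cls$mirna == "m1"], "high_confidence")
  expect_equal(cls$category[cls$mirna == "m3"], "non_specific")
  # dropout: a miRNA too dilute to amplify is undetected -> no_interaction
  spec_do <- ct_sim_spec("weak", enrichment = 4, baseline_ct = 45)
  plate_do <- gen_ct_experiment(spec_do, rng_seed = 10)
  expect_true(all(is.na(plate_do$ct[plate_do$assay == "weak" &
                                      plate_do$condition == "wt_utr"])))
  cls_do <- mitrap_classify(plate_do)
  expect_equal(cls_do$category, "no_interaction")
})

test_that("with replicate noise the 95% CI covers the true enrichment in >=90% of simulations", {
  true_e <- 4
  spec <- ct_sim_spec("m", enrichment = true_e, noise_sd = 0.3)
  covered <- 0L
  for (i in 1:500) {
    plate <- gen_ct_experiment(spec, rng_seed = 20000 + i)
    cls <- mitrap_classify(plate)
    if (!is.na(cls$nrq) && cls$ci_low <= true_e && true_e <= cls$ci_high) {
      covered <- covered + 1L
    }
  }
  expect_gte(covered / 500, 0.90)
})

test_that("null enrichment almost never yields high-confidence calls", {
  spec <- ct_sim_spec("m", enrichment = 1, noise_sd = 0.3)
  hc <- 0L
  for (i in 1:200) {
    plate <- gen_ct_experiment(spec, rng_seed = 40000 + i)
    cls <- mitrap_classify(plate)
    if (identical(cls$category, "high_confidence")) hc <- hc + 1L
  }
  expect_lte(hc / 200, 0.05)
})
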
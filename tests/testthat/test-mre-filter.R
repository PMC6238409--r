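# A reusable planted universe: 3 miRNAs, 4 sites, known attributes.
make_planted_world <- function(seed = 42) {
  mir <- gen_mirnas(3, rng_seed = seed)
  spec <- tibble::tibble(
    mirna = c(1, 2, 3, 1),
    position = c(30, 90, 150, 220),
    site_type = c("8mer", "7mer-m8", "7mer-A1", "6mer")
  )
  g <- gen_utr_with_planted_sites(280, spec, mir, rng_seed = seed + 1)
  list(mirnas = mir, utr = g$utr, truth = g$truth)
}

test_that("site conservation counts disrupted species against an assessable denominator", {
  w <- make_planted_world()
  # species 1..2 disrupt every site, 3..10 retain everything
  probs <- c(0, 0, rep(1, 8))
  aln <- gen_ortholog_alignment(w$utr, w$truth, w$mirnas, n_species = 10,
                                conservation_probs = probs, rng_seed = 7,
                                background_sub_rate = 0, gap_rate = 0)
  for (i in seq_len(nrow(w$truth))) {
    mi <- w$mirnas[match(w$truth$mirna[i], w$mirnas$name), ]
    cons <- site_conservation(w$truth[i, ], aln$alignment, mi)
    expect_equal(cons$fraction, 8 / 10)
    expect_equal(cons$n_assessable, 10L)
  }
  # all species identical to reference -> 1.0
  aln1 <- gen_ortholog_alignment(w$utr, w$truth, w$mirnas, n_species = 5,
                                 conservation_probs = 1, rng_seed = 8,
                                 background_sub_rate = 0, gap_rate = 0)
  cons1 <- annotate_conservation(w$truth, aln1$alignment, w$mirnas)
  expect_true(all(cons1$conservation == 1))
})

test_that("an all-gap orthologous window leaves conservation undefined and failing", {
  w <- make_planted_world(3)
  site <- w$truth[1, ]
  gapped <- strsplit(w$utr, "")[[1]]
  gapped[site$start:site$end] <- "-"
  aln <- ortholog_alignment(
    c(mmu = w$utr, spA = paste(gapped, collapse = ""),
      spB = paste(gapped, collapse = "")),
    reference = "mmu"
  )
  mi <- w$mirnas[match(site$mirna, w$mirnas$name), ]
  cons <- site_conservation(site, aln, mi)
  expect_false(cons$defined)
  expect_true(is.na(cons$fraction))
  out <- apply_funnel(annotate_conservation(site, aln, w$mirnas),
                      mirnas = w$mirnas)
  expect_equal(out$report$stages$n_hits[4], 0L)
})

test_that("funnel stages drop mismatches, wobbly 6mers, unconserved and non-required-species sites", {
  sites <- tibble::tibble(
    mirna = c("a", "b", "c", "d", "e", "f"),
    start = c(10, 40, 70, 100, 130, 160),
    end = c(17, 45, 76, 105, 136, 167),
    site_type = c("8mer", "6mer", "7mer-m8", "6mer", "7mer-A1", "8mer"),
    n_wobble = c(0L, 1L, 1L, 0L, 0L, 0L),
    n_mismatch = c(0L, 0L, 0L, 1L, 0L, 0L),
    conservation = c(0.9, 0.9, 0.9, 0.9, 0.5, 1.0),
    species = list(c("mmu", "hsa"), c("mmu", "hsa"), c("mmu", "hsa"),
                   c("mmu", "hsa"), c("mmu", "hsa"), "mmu")
  )
  out <- apply_funnel(sites)
  counts <- out$report$stages$n_hits
  # universe 6; drop d (mismatch) -> 5; drop b (6mer+wobble) -> 4;
  # drop e (conservation 0.5) -> 3; drop f (mouse-only) -> 2
  expect_equal(counts, c(6L, 5L, 4L, 3L, 2L))
  expect_setequal(out$sites$mirna, c("a", "c"))
  expect_equal(out$report$unique_mre_count, 2L)
  expect_equal(out$report$unique_mirna_count, 2L)
})

test_that("funnel is monotone and stage order 2/3 commutes on random universes", {
  withr::local_seed(1234)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    sites <- tibble::tibble(
      mirna = sample(letters[1:8], n, replace = TRUE),
      start = sample(1:500, n, replace = TRUE),
      site_type = sample(c("6mer", "7mer-A1", "7mer-m8", "8mer"), n, TRUE),
      n_wobble = sample(0:1, n, TRUE),
      n_mismatch = sample(0:1, n, TRUE),
      conservation = round(runif(n), 2),
      species = lapply(seq_len(n), function(.)
        sample(c("mmu", "hsa", "rno"), sample(1:3, 1)))
    )
    sites$end <- sites$start +
      c("6mer" = 5L, "7mer-A1" = 6L, "7mer-m8" = 6L, "8mer" = 7L)[sites$site_type]
    out <- apply_funnel(sites)
    expect_true(all(diff(out$report$stages$n_hits) <= 0))
    # stages 2 and 3 commute
    s23 <- dplyr::filter(sites, n_mismatch == 0L)
    s23 <- dplyr::filter(s23, !(site_type == "6mer" & n_wobble >= 1L))
    s32 <- dplyr::filter(sites, !(site_type == "6mer" & n_wobble >= 1L))
    s32 <- dplyr::filter(s32, n_mismatch == 0L)
    expect_identical(s23, s32)
    expect_equal(out$report$stages$n_hits[3], nrow(s23))
  }
})

test_that("empty universe flows through with all-zero stage counts", {
  empty <- tibble::tibble(
    mirna = character(), start = integer(), end = integer(),
    site_type = character(), n_wobble = integer(), n_mismatch = integer(),
    conservation = double(), species = list()
  )
  out <- apply_funnel(empty)
  expect_equal(out$report$stages$n_hits, rep(0L, 5))
  expect_equal(out$report$unique_mre_count, 0L)
})

test_that("published-count discrepancies are surfaced in notes, not resolved", {
  sites <- tibble::tibble(
    mirna = "a", start = 10L, end = 17L, site_type = "8mer",
    n_wobble = 0L, n_mismatch = 0L, conservation = 1,
    species = list(c("mmu", "hsa"))
  )
  out <- apply_funnel(sites, reference_counts = c(
    universe = 1, no_6mer_wobble = 2, no_6mer_wobble = 3
  ))
  # both conflicting published values for the same stage are reported
  expect_length(out$report$notes, 2L)
  expect_match(out$report$notes[1], "unresolved")
  expect_equal(out$report$stages$n_hits[3], 1L)
})

test_that("redundancy summary counts shared MREs and multi-site miRNAs from planted truth", {
  # 3 MRE groups shared by >=2 miRNAs, 4 miRNAs with >=2 MRE groups
  sites <- tibble::tibble(
    mirna = c("m1", "m2",  "m1", "m3",  "m2", "m4",  "m3", "m4", "m1"),
    start = c(10L, 12L,    50L, 52L,    90L, 91L,    130L, 160L, 200L),
    site_type = "8mer"
  )
  sites$end <- sites$start + 7L # 8-nt footprints overlap by >= 6 within a group
  red <- redundancy_summary(sites)
  expect_equal(red$mres_with_multiple_mirnas, 3L)
  expect_equal(red$mirnas_with_multiple_mres, 4L)
  # single site, single miRNA -> no redundancy
  one <- redundancy_summary(sites[1, ])
  expect_equal(one$mres_with_multiple_mirnas, 0L)
  expect_equal(one$mirnas_with_multiple_mres, 0L)
})

test_that("prediction-table import maps the column contract onto the site schema", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    mirna = c("miR-x", "miR-y"), start = c(5L, 30L),
    type = c("8mer", "6mer"), n_wobble = c(0L, 1L), n_mismatch = c(0L, 0L),
    conservation = c(0.95, 0.4), species_flags = c("mmu,hsa", "mmu")
  ), path)
  sites <- read_prediction_table(path)
  expect_equal(sites$end, c(12L, 35L))
  expect_equal(sites$canonical, c(TRUE, FALSE))
  out <- apply_funnel(sites)
  expect_equal(out$report$stages$n_hits, c(2L, 2L, 1L, 1L, 1L))
})
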
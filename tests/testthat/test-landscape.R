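test_that("a single peak paints a clipped 51-nt plateau with no overlaps", {
  l <- build_landscape(
    tibble::tibble(mirna = "m", position = 100, nrq = 4), utr_length = 300
  )
  expect_equal(l$track$height[75:125], rep(4, 51))
  expect_equal(sum(l$track$height > 0), 51L)
  expect_equal(nrow(l$overlaps), 0L)
  # clipping at the UTR edge keeps coordinates in range
  l2 <- build_landscape(
    tibble::tibble(mirna = "m", position = 5, nrq = 1), utr_length = 300
  )
  expect_equal(l2$peaks$start, 1L)
  expect_equal(sum(l2$track$height > 0), 30L)
})

test_that("two nearby peaks max-composite and flag their overlap interval", {
  l <- build_landscape(
    tibble::tibble(mirna = c("a", "b"), position = c(100, 130),
                   nrq = c(4, 2)),
    utr_length = 300
  )
  expect_equal(l$overlaps$start, 105L)
  expect_equal(l$overlaps$end, 125L)
  # max compositing: the taller peak wins inside the overlap
  expect_equal(unique(l$track$height[105:125]), 4)
  expect_equal(unique(l$track$height[126:155]), 2)
  expect_error(
    build_landscape(tibble::tibble(mirna = "a", position = 500, nrq = 1),
                    utr_length = 300),
    "outside"
  )
})

test_that("track coverage equals the union of peak intervals on random plantings", {
  withr::local_seed(33)
  for (i in 1:20) {
    n <- sample(1:12, 1)
    sites <- tibble::tibble(
      mirna = paste0("m", seq_len(n)),
      position = sample(1:800, n),
      nrq = runif(n, 0.5, 10)
    )
    l <- build_landscape(sites, utr_length = 800)
    covered <- rep(FALSE, 800)
    for (j in seq_len(n)) {
      covered[max(1, sites$position[j] - 25):min(800, sites$position[j] + 25)] <- TRUE
    }
    expect_equal(l$track$height > 0, covered)
  }
})

test_that("cooperative pairing applies the 8-50 nt spacing band", {
  cfg <- landscape_config()
  s <- tibble::tibble(mirna = c("a", "b"), position = c(100L, 140L))
  expect_equal(nrow(cooperative_pairs(s, cfg)), 1L)
  expect_equal(cooperative_pairs(s, cfg)$spacing, 40L)
  s_close <- tibble::tibble(mirna = c("a", "b"), position = c(100L, 104L))
  expect_equal(nrow(cooperative_pairs(s_close, cfg)), 0L)
  s_far <- tibble::tibble(mirna = c("a", "b"), position = c(100L, 160L))
  expect_equal(nrow(cooperative_pairs(s_far, cfg)), 0L)
})

test_that("pairs of the same miRNA or of miRNAs sharing overlapping MREs are vetoed", {
  cfg <- landscape_config()
  same <- tibble::tibble(mirna = c("a", "a"), position = c(100L, 130L))
  expect_equal(nrow(cooperative_pairs(same, cfg)), 0L)
  # a and b overlap at ~200, so their well-spaced 100/130 pair is also vetoed
  sharers <- tibble::tibble(
    mirna = c("a", "b", "a", "b"),
    position = c(100L, 130L, 200L, 203L),
    start = c(100L, 130L, 200L, 203L),
    end = c(107L, 137L, 207L, 210L)
  )
  expect_equal(nrow(cooperative_pairs(sharers, cfg)), 0L)
})

test_that("pair detection equals the brute-force all-pairs oracle", {
  withr::local_seed(404)
  cfg <- landscape_config()
  for (i in 1:30) {
    n <- sample(2:10, 1)
    s <- tibble::tibble(
      mirna = paste0("m", seq_len(n)), # distinct miRNAs, point sites
      position = sample(1:400, n)
    )
    got <- cooperative_pairs(s, cfg)
    want <- 0L
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        d <- abs(s$position[a] - s$position[b])
        if (d >= 8 && d <= 50) want <- want + 1L
      }
    }
    expect_equal(nrow(got), want)
    # symmetry/anti-reflexivity: no self pairs, each unordered pair once
    expect_false(any(got$mirna_a == got$mirna_b))
    expect_false(any(duplicated(
      paste(pmin(got$mirna_a, got$mirna_b), pmax(got$mirna_a, got$mirna_b))
    )))
    # shrinking the band never adds pairs
    tight <- cooperative_pairs(s, landscape_config(coop_min = 12, coop_max = 40))
    expect_lte(nrow(tight), nrow(got))
  }
})

test_that("three well-separated planted groups yield exactly three cluster regions", {
  sites <- tibble::tibble(
    mirna = paste0("m", 1:9),
    position = c(100, 115, 130, 300, 315, 330, 500, 515, 530),
    nrq = 2
  )
  l <- build_landscape(sites, utr_length = 700)
  cl <- cluster_regions(l)
  expect_equal(nrow(cl), 3L)
  expect_equal(cl$n_peaks, rep(3L, 3))
  expect_true(all(cl$has_cooperative_pair))
  # one peak -> one region equal to its interval
  one <- build_landscape(tibble::tibble(mirna = "m", position = 100, nrq = 1),
                         utr_length = 300)
  cl1 <- cluster_regions(one)
  expect_equal(nrow(cl1), 1L)
  expect_equal(c(cl1$start, cl1$end), c(75L, 125L))
})

test_that("cluster count is non-increasing in the peak half-width", {
  withr::local_seed(61)
  for (i in 1:15) {
    n <- sample(2:10, 1)
    sites <- tibble::tibble(mirna = paste0("m", seq_len(n)),
                            position = sample(1:800, n), nrq = 1)
    counts <- vapply(c(5L, 15L, 25L, 40L, 60L), function(hw) {
      cfg <- landscape_config(half_width = hw)
      nrow(cluster_regions(build_landscape(sites, 800, cfg), cfg))
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("track and interval writers emit valid 0-based BED conversions", {
  l <- build_landscape(
    tibble::tibble(mirna = c("a", "b"), position = c(50, 200), nrq = c(2, 3)),
    utr_length = 300
  )
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed6(dplyr::mutate(l$peaks, name = mirna, score = height), bed)
  b <- readr::read_tsv(bed, col_names = FALSE, show_col_types = FALSE)
  expect_equal(b$X2, l$peaks$start - 1L)
  expect_equal(b$X3, l$peaks$end)
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(l$track, bg)
  g <- readr::read_tsv(bg, col_names = FALSE, show_col_types = FALSE)
  # run-length intervals tile the UTR exactly
  expect_equal(g$X2[1], 0)
  expect_equal(g$X3[nrow(g)], 300)
  expect_true(all(g$X2[-1] == g$X3[-nrow(g)]))
})
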
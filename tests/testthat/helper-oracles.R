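# Independent brute-force oracles. These deliberately re-derive every
# result from first principles with naive loops so they share no code
# path with the package implementation.

oracle_complement <- c(A = "T", C = "G", G = "C", T = "A")

# Naive sliding-window substring-equality scan for hexamer signals.
oracle_polya_scan <- function(seq, variants, region_end = nchar(seq)) {
  seq <- toupper(seq)
  hits <- list()
  for (p in seq_len(max(0L, nchar(seq) - 5L))) {
    if (p > region_end) next
    w <- substr(seq, p, p + 5L)
    if (w %in% variants) hits[[length(hits) + 1L]] <- list(p = p, w = w)
  }
  tibble::tibble(
    position = vapply(hits, function(h) h$p, integer(1)),
    hexamer = vapply(hits, function(h) h$w, character(1))
  )
}

# Pair classification written out longhand.
oracle_pair <- function(t, m) {
  if (t %in% c("N", "-") || m %in% c("N", "-")) return("none")
  if (t == oracle_complement[[m]]) return("wc")
  if ((t == "G" && m == "T") || (t == "T" && m == "G")) return("wobble")
  "mismatch"
}

# Exhaustive site oracle: tests every (position, type) combination with
# explicit per-position pair checks against the config's edit budget.
oracle_scan_mres <- function(utr, mirnas, allow_wobble = FALSE,
                             allow_mismatch = FALSE,
                             report_all_types = FALSE) {
  utr <- toupper(chartr("Uu", "Tt", utr))
  uc <- strsplit(utr, "")[[1]]
  n <- length(uc)
  max_w <- if (allow_wobble) 1L else 0L
  max_m <- if (allow_mismatch) 1L else 0L
  rows <- list()
  for (k in seq_len(nrow(mirnas))) {
    mc <- strsplit(toupper(chartr("Uu", "Tt", mirnas$sequence[[k]])), "")[[1]]
    for (core in seq_len(max(0L, n - 5L))) {
      # pair classes of the core (UTR core..core+5 vs miRNA 7..2)
      core_cls <- character(6)
      for (q in 0:5) core_cls[q + 1L] <- oracle_pair(uc[core + q], mc[7L - q])
      m8_cls <- if (core >= 2L) oracle_pair(uc[core - 1L], mc[8L]) else "none"
      a1_ok <- core + 6L <= n && uc[core + 6L] == "A"
      found <- list()
      for (type in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
        cls <- switch(type,
          "8mer" = c(core_cls, m8_cls), "7mer-m8" = c(core_cls, m8_cls),
          core_cls
        )
        if (type %in% c("8mer", "7mer-A1") && !a1_ok) next
        if (any(cls == "none")) next
        nw <- sum(cls == "wobble"); nm <- sum(cls == "mismatch")
        if (nw > max_w || nm > max_m) next
        start <- if (type %in% c("8mer", "7mer-m8")) core - 1L else core
        len <- c("8mer" = 8L, "7mer-m8" = 7L, "7mer-A1" = 7L, "6mer" = 6L)[[type]]
        found[[type]] <- tibble::tibble(
          mirna = mirnas$name[[k]], start = start, end = start + len - 1L,
          site_type = type, n_wobble = nw, n_mismatch = nm
        )
        if (!report_all_types) break
      }
      rows <- c(rows, found)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(mirna = character(), start = integer(),
                          end = integer(), site_type = character(),
                          n_wobble = integer(), n_mismatch = integer()))
  }
  dplyr::arrange(out, start, mirna,
                 match(site_type, c("8mer", "7mer-m8", "7mer-A1", "6mer")))
}

# Exact Mann-Whitney two-sided p by utils::combn enumeration of which
# pooled midranks fall in group a.
oracle_mw_p <- function(a, b) {
  ranks <- rank(c(a, b))
  na <- length(a)
  w_obs <- sum(ranks[seq_len(na)])
  sums <- apply(utils::combn(length(ranks), na), 2L,
                function(idx) sum(ranks[idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(sums <= w_obs + eps), mean(sums >= w_obs - eps)))
}

random_dna_str <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

site_key <- function(tbl) {
  paste(tbl$mirna, tbl$start, tbl$site_type, tbl$n_wobble, tbl$n_mismatch,
        sep = "|")
}
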
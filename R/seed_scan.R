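# Site lengths implied by type, and type precedence (strongest first)
.SITE_LENGTH <- c("8mer" = 8L, "7mer-m8" = 7L, "7mer-A1" = 7L, "6mer" = 6L)
.TYPE_ORDER <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Site-type precedence rank (1 = strongest)
#' @param type Character vector of site types.
#' @return Integer ranks; 8mer = 1, 7mer-m8 = 2, 7mer-A1 = 3, 6mer = 4.
#' @export
site_type_rank <- function(type) match(type, .TYPE_ORDER)

#' Build a table of mature miRNA records
#'
#' A miRNA record carries the mature sequence (5'->3', at least 8 nt), the
#' 6-nt seed (nucleotides 2-7), the extended 7-nt seed (nucleotides 2-8)
#' and a species set. Sequences may be RNA or DNA; seeds are reported in
#' the input alphabet, pairing is computed on the internal DNA form.
#'
#' @param name Character vector of miRNA names.
#' @param sequence Character vector of mature sequences (5'->3').
#' @param species List of character vectors of species tags (recycled).
#' @return Tibble with columns `name`, `sequence`, `seed6`, `seed7`,
#'   `species` (list column).
#' @export
#' @examples
#' mirna_records("mmu-miR-375", "UUUGUUCGUUCGGCUCGCGUGA", list("mmu"))
mirna_records <- function(name, sequence, species = list(character())) {
  if (length(name) != length(sequence)) {
    abort("name and sequence must have equal length")
  }
  if (any(nchar(sequence) < 8L)) {
    abort("mature miRNA sequences must be at least 8 nt")
  }
  sequence <- toupper(sequence)
  vapply(sequence, normalize_seq, character(1), what = "miRNA sequence")
  if (!is.list(species)) species <- list(species)
  species <- rep_len(species, length(name))
  tibble(
    name = as.character(name),
    sequence = sequence,
    seed6 = substring(sequence, 2L, 7L),
    seed7 = substring(sequence, 2L, 8L),
    species = species
  )
}

#' Seed-match configuration
#'
#' @param allow_wobble Permit at most one G:U wobble pair among the pairing
#'   positions of a site (target G : miRNA U, or target U : miRNA G).
#' @param allow_mismatch Permit at most one mismatched pair.
#' @param report_all_types Report every satisfiable site type at a position
#'   instead of only the strongest under the precedence
#'   8mer > 7mer-m8 > 7mer-A1 > 6mer.
#' @return A list of class `seed_match_config`.
#' @export
seed_match_config <- function(allow_wobble = FALSE, allow_mismatch = FALSE,
                              report_all_types = FALSE) {
  structure(
    list(
      allow_wobble = isTRUE(allow_wobble),
      allow_mismatch = isTRUE(allow_mismatch),
      report_all_types = isTRUE(report_all_types)
    ),
    class = "seed_match_config"
  )
}

# Pairing layout of an 8-nt target window w[1..8] (5'->3') against the
# miRNA 5' end (antiparallel): w[1] opposes miRNA nt 8 (the m8 extension),
# w[2..7] oppose miRNA nt 7..2 (the 6mer seed core), and w[8] sits across
# miRNA nt 1 (the A1 position, which must be target adenine and is not a
# pairing position).
classify_window_chars <- function(w, m, config) {
  core <- pair_class(w[2:7], m[7:2])
  m8 <- pair_class(w[1L], m[8L])
  a1_ok <- w[8L] == "A"
  max_w <- if (config$allow_wobble) 1L else 0L
  max_m <- if (config$allow_mismatch) 1L else 0L
  rows <- list()
  for (type in .TYPE_ORDER) {
    pairing <- switch(type,
      "8mer" = c(core, m8),
      "7mer-m8" = c(core, m8),
      "7mer-A1" = core,
      "6mer" = core
    )
    needs_a1 <- type %in% c("8mer", "7mer-A1")
    if (needs_a1 && !a1_ok) next
    if (any(pairing == "none")) next
    nw <- sum(pairing == "wobble")
    nm <- sum(pairing == "mismatch")
    if (nw > max_w || nm > max_m) next
    rows[[type]] <- tibble(
      site_type = type, n_wobble = nw, n_mismatch = nm,
      canonical = nw == 0L && nm == 0L
    )
    if (!config$report_all_types) break
  }
  if (length(rows) == 0L) NULL else bind_rows(rows)
}

#' Classify one 8-nt target window against a miRNA seed region
#'
#' Evaluates antiparallel pairing of the window against miRNA nucleotides
#' 2-7 (seed core), nucleotide 8 (m8 extension) and the A1 position (target
#' adenine opposite miRNA nucleotide 1, required regardless of the miRNA's
#' own nucleotide 1) and returns the satisfiable site type(s) with their
#' wobble/mismatch counts. Windows at UTR edges may be padded with `N`,
#' which never pairs.
#'
#' @param utr_window 8-nt target window, 5'->3' (pad with `N` at edges).
#' @param mirna A one-row miRNA tibble from [mirna_records()].
#' @param config A [seed_match_config()].
#' @return `NULL` when no type is satisfiable, otherwise a tibble with
#'   columns `site_type`, `n_wobble`, `n_mismatch`, `canonical` (one row
#'   unless `report_all_types`). The strongest type comes first.
#' @export
classify_window <- function(utr_window, mirna, config = seed_match_config()) {
  w <- seq_chars(normalize_seq(utr_window, what = "utr_window"))
  if (length(w) != 8L) abort("utr_window must be exactly 8 nt")
  m <- seq_chars(normalize_seq(mirna$sequence[[1L]], what = "miRNA sequence"))
  classify_window_chars(w, m, config)
}

#' Enumerate miRNA recognition elements in a UTR
#'
#' Applies [classify_window()] at every position for every miRNA. Site
#' start is the 5'-most UTR nucleotide of the match: for 8mer/7mer-m8 sites
#' this is the nucleotide opposite miRNA nt 8; 7mer-A1 and 6mer sites start
#' at the seed-core match (the A1 adenine lies at the site's 3' end). With
#' `report_all_types = TRUE` and both relaxations enabled, the result is
#' the full unique-hit universe keyed by `(mirna, start, site_type)`.
#'
#' @param utr UTR sequence (string; RNA accepted).
#' @param mirnas miRNA tibble from [mirna_records()].
#' @param config A [seed_match_config()].
#' @return Tibble with columns `mirna`, `start`, `end` (1-based inclusive),
#'   `site_type`, `n_wobble`, `n_mismatch`, `canonical`, sorted by start,
#'   miRNA, then type precedence.
#' @export
scan_mres <- function(utr, mirnas, config = seed_match_config()) {
  empty <- tibble(
    mirna = character(), start = integer(), end = integer(),
    site_type = character(), n_wobble = integer(), n_mismatch = integer(),
    canonical = logical()
  )
  if (nrow(mirnas) == 0L) return(empty)
  utr <- normalize_seq(utr, what = "utr")
  n <- nchar(utr)
  if (n == 0L) abort("utr must be non-empty")
  if (n < 6L) return(empty)
  chars <- seq_chars(utr)
  out <- vector("list", nrow(mirnas))
  for (i in seq_len(nrow(mirnas))) {
    m <- seq_chars(normalize_seq(mirnas$sequence[[i]], what = "miRNA sequence"))
    hits <- list()
    # core start c: 6mer seed core occupies UTR positions c..c+5; the full
    # 8-window spans c-1..c+6 with N sentinels beyond the UTR edges
    for (c_start in seq_len(n - 5L)) {
      w <- c(
        if (c_start >= 2L) chars[c_start - 1L] else "N",
        chars[c_start:(c_start + 5L)],
        if (c_start + 6L <= n) chars[c_start + 6L] else "N"
      )
      ann <- classify_window_chars(w, m, config)
      if (is.null(ann)) next
      len <- .SITE_LENGTH[ann$site_type]
      start <- ifelse(ann$site_type %in% c("8mer", "7mer-m8"),
                      c_start - 1L, c_start)
      ann$start <- as.integer(start)
      ann$end <- as.integer(start + len - 1L)
      hits[[length(hits) + 1L]] <- ann
    }
    if (length(hits) > 0L) {
      h <- bind_rows(hits)
      h$mirna <- mirnas$name[[i]]
      out[[i]] <- h
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) return(empty)
  res %>%
    select("mirna", "start", "end", "site_type", "n_wobble", "n_mismatch",
           "canonical") %>%
    arrange(.data$start, .data$mirna, site_type_rank(.data$site_type))
}
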
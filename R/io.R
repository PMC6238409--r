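#' Read a UTR (or other single-sequence) FASTA file
#'
#' Reads the first record of a FASTA file and returns the normalized DNA
#' sequence (RNA is transcribed to the internal DNA alphabet).
#'
#' @param path FASTA file path.
#' @return A single character string.
#' @export
read_utr_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort("FASTA file contains no records")
  normalize_seq(as.character(set[[1L]]), what = basename(path))
}

#' Read mature miRNA sequences from a miRBase-style FASTA file
#'
#' Headers are parsed in the miRBase `mature.fa` dialect:
#' `>mmu-miR-375 MIMAT0000739 Mus musculus miR-375`. The species tag is the
#' three-letter prefix of the record name (e.g. `mmu`, `hsa`). Records whose
#' name minus the species prefix is shared across several species are
#' aggregated so each returned miRNA carries the full species set; the
#' sequence kept is the `reference_species` one when present.
#'
#' @param path FASTA file path.
#' @param reference_species Species prefix whose sequence/name is kept per
#'   aggregated family (default `"mmu"`).
#' @param aggregate_species Collapse same-named miRNAs across species into a
#'   species set (default `TRUE`).
#' @return A miRNA tibble as produced by [mirna_records()].
#' @export
read_mirna_fasta <- function(path, reference_species = "mmu",
                             aggregate_species = TRUE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort("miRNA FASTA file contains no records")
  full_names <- names(set)
  name <- vapply(strsplit(full_names, "\\s+"), `[[`, character(1), 1L)
  species <- ifelse(grepl("^[a-z]{3,4}-", name), sub("-.*$", "", name), NA_character_)
  seqs <- vapply(seq_along(set), function(i) as.character(set[[i]]), character(1))
  tbl <- tibble(name = name, sequence = seqs, species = species)
  if (!aggregate_species) {
    return(mirna_records(tbl$name, tbl$sequence,
                         species = as.list(tbl$species)))
  }
  tbl$stem <- ifelse(is.na(tbl$species), tbl$name,
                     sub("^[a-z]{3,4}-", "", tbl$name))
  agg <- tbl %>%
    group_by(.data$stem) %>%
    summarise(
      species = list(sort(unique(stats::na.omit(.data$species)))),
      name = if (any(.data$species %in% reference_species)) {
        .data$name[match(reference_species, .data$species)]
      } else .data$name[1L],
      sequence = if (any(.data$species %in% reference_species)) {
        .data$sequence[match(reference_species, .data$species)]
      } else .data$sequence[1L],
      .groups = "drop"
    )
  mirna_records(agg$name, agg$sequence, species = agg$species)
}

#' Read an ortholog multiple alignment from aligned FASTA
#'
#' Species names are the first whitespace-delimited token of each record id.
#'
#' @param path Aligned FASTA path (gap character `-`).
#' @param reference Species name of the reference sequence.
#' @return An [ortholog_alignment()] object.
#' @export
read_ortholog_alignment <- function(path, reference) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- vapply(seq_along(set), function(i) as.character(set[[i]]), character(1))
  ortholog_alignment(setNames(seqs, ids), reference = reference)
}

#' Read a qPCR plate table
#'
#' Expects columns `sample, assay, condition, replicate, ct, rt_control`.
#' The `ct` column may contain `"undetermined"` (any case) or blanks, which
#' become `NA` (undetermined is encoded distinctly from every numeric Ct).
#'
#' @param path CSV or TSV file path (delimiter sniffed from the extension).
#' @return A tibble of Ct records.
#' @export
read_plate_table <- function(path) {
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  raw <- reader(path, show_col_types = FALSE,
                col_types = readr::cols(.default = readr::col_character()))
  needed <- c("sample", "assay", "condition", "replicate", "ct", "rt_control")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    abort(paste("plate table is missing columns:", paste(missing, collapse = ", ")))
  }
  ct <- suppressWarnings(as.numeric(raw$ct))
  undet <- grepl("^\\s*(undetermined|undefined|na)?\\s*$", raw$ct, ignore.case = TRUE)
  ct[undet] <- NA_real_
  if (any(!undet & is.na(ct))) abort("plate table has unparseable ct values")
  if (any(ct <= 0, na.rm = TRUE)) abort("ct values must be positive")
  tibble(
    sample = raw$sample,
    assay = raw$assay,
    condition = raw$condition,
    replicate = as.integer(raw$replicate),
    ct = ct,
    rt_control = tolower(raw$rt_control) %in% c("true", "t", "1", "yes")
  )
}

#' Import a pre-computed MRE prediction table
#'
#' Maps an external prediction TSV onto the site-table contract used by
#' [apply_funnel()]. Required columns: `mirna, start, type`; optional:
#' `end, n_wobble, n_mismatch, conservation, species_flags` (comma-separated
#' species tags). Missing wobble/mismatch counts default to 0; `end` is
#' derived from the site type when absent.
#'
#' @param path TSV file path.
#' @return A site tibble compatible with the scanner output.
#' @export
read_prediction_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("mirna", "start", "type")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    abort(paste("prediction table is missing columns:",
                paste(missing, collapse = ", ")))
  }
  type <- as.character(raw$type)
  bad <- setdiff(unique(type), names(.SITE_LENGTH))
  if (length(bad) > 0L) {
    abort(paste("unknown site types:", paste(bad, collapse = ", ")))
  }
  out <- tibble(
    mirna = as.character(raw$mirna),
    start = as.integer(raw$start),
    end = if ("end" %in% names(raw)) as.integer(raw$end) else
      as.integer(raw$start) + unname(.SITE_LENGTH[type]) - 1L,
    site_type = type,
    n_wobble = if ("n_wobble" %in% names(raw)) as.integer(raw$n_wobble) else 0L,
    n_mismatch = if ("n_mismatch" %in% names(raw)) as.integer(raw$n_mismatch) else 0L
  )
  out$canonical <- out$n_wobble == 0L & out$n_mismatch == 0L
  if ("conservation" %in% names(raw)) out$conservation <- as.numeric(raw$conservation)
  if ("species_flags" %in% names(raw)) {
    out$species <- strsplit(as.character(raw$species_flags), ",\\s*")
  }
  arrange(out, .data$start, .data$mirna, .data$site_type)
}

#' Convert a 1-based interval tibble to BED6 and write it
#'
#' Converts 1-based inclusive `start`/`end` columns to BED's 0-based
#' half-open convention.
#'
#' @param x Tibble with `start`, `end` and optionally `name`/`score` columns.
#' @param path Output path.
#' @param chrom Chromosome/sequence name to stamp on every row.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(x, path, chrom = "utr") {
  bed <- tibble(
    chrom = chrom,
    start = as.integer(x$start) - 1L,
    end = as.integer(x$end),
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = "+"
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write a per-position track as bedGraph
#'
#' @param track Tibble with `position` (1-based) and `height` columns.
#' @param path Output path.
#' @param chrom Sequence name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, chrom = "utr") {
  runs <- track %>%
    arrange(.data$position) %>%
    mutate(run = cumsum(.data$height != lag(.data$height, default = Inf))) %>%
    group_by(.data$run) %>%
    summarise(
      start = min(.data$position) - 1L,
      end = max(.data$position),
      value = .data$height[1L],
      .groups = "drop"
    )
  readr::write_tsv(
    tibble(chrom = chrom, start = runs$start, end = runs$end, value = runs$value),
    path, col_names = FALSE
  )
  invisible(path)
}
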
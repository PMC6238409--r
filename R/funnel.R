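#' Construct an ortholog UTR alignment
#'
#' @param sequences Named character vector or list of gapped sequences
#'   (gap character `-`), all of equal width; names are species tags.
#' @param reference Species name of the reference (ungapping it must
#'   reproduce the input UTR; the constructor checks it carries no
#'   unexpected characters).
#' @return An object of class `ortholog_alignment` with elements
#'   `sequences`, `reference`, `width` and `ref_columns` (alignment column
#'   of each ungapped reference position).
#' @export
ortholog_alignment <- function(sequences, reference) {
  sequences <- unlist(sequences)
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    abort("all alignment sequences must be named by species")
  }
  sequences <- vapply(
    sequences, normalize_seq, character(1),
    allow_gap = TRUE, what = "alignment sequence"
  )
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    abort("all gapped sequences must have equal length")
  }
  if (!reference %in% names(sequences)) {
    abort(sprintf("reference species '%s' is not in the alignment", reference))
  }
  ref_chars <- seq_chars(sequences[[reference]])
  structure(
    list(
      sequences = sequences,
      reference = reference,
      width = widths[[1L]],
      ref_columns = which(ref_chars != "-")
    ),
    class = "ortholog_alignment"
  )
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat(sprintf(
    "<ortholog_alignment> %d species x %d columns (reference: %s, %d ungapped nt)\n",
    length(x$sequences), x$width, x$reference, length(x$ref_columns)
  ))
  invisible(x)
}

#' Species present in an alignment
#' @param aln An [ortholog_alignment()].
#' @param include_reference Keep the reference species in the result.
#' @return Character vector of species names.
#' @export
alignment_species <- function(aln, include_reference = FALSE) {
  sp <- names(aln$sequences)
  if (!include_reference) sp <- setdiff(sp, aln$reference)
  sp
}

#' Candidate-funnel configuration
#'
#' @param conservation_threshold Minimum fraction of assessable clade
#'   species in which a site must be conserved (default 0.85).
#' @param conservation_clade Species subset used for the conservation
#'   denominator (default `NULL`: all non-reference species).
#' @param required_species Species tags a site's miRNA must carry to
#'   survive the species filter (default `"hsa"`).
#' @param drop_mismatch Drop sites with any mismatched pair (default TRUE).
#' @param drop_6mer_wobble Drop 6mer sites containing a G:U wobble
#'   (default TRUE).
#' @param max_gap_fraction Species whose aligned site window exceeds this
#'   gap fraction are excluded from the conservation denominator
#'   (default 0.5).
#' @param conservation_mode `"site"`: an orthologous window counts as
#'   conserved when it contains an equal-or-stronger site for the same
#'   miRNA with no more wobble+mismatch edits than the reference site;
#'   `"identity"`: the gap-stripped window must equal the reference site
#'   sequence exactly.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(conservation_threshold = 0.85,
                          conservation_clade = NULL,
                          required_species = "hsa",
                          drop_mismatch = TRUE,
                          drop_6mer_wobble = TRUE,
                          max_gap_fraction = 0.5,
                          conservation_mode = c("site", "identity")) {
  if (conservation_threshold <= 0 || conservation_threshold > 1) {
    abort("conservation_threshold must be in (0, 1]")
  }
  structure(
    list(
      conservation_threshold = conservation_threshold,
      conservation_clade = conservation_clade,
      required_species = required_species,
      drop_mismatch = isTRUE(drop_mismatch),
      drop_6mer_wobble = isTRUE(drop_6mer_wobble),
      max_gap_fraction = max_gap_fraction,
      conservation_mode = match.arg(conservation_mode)
    ),
    class = "filter_config"
  )
}

# Does a gap-stripped orthologous window carry the site? The window is
# padded with one UTR-context base on each side inside the alignment so a
# site shifted by a gap column is not missed within the same footprint.
.window_has_site <- function(window, mirna_row, site_row, mode) {
  if (mode == "identity") {
    return(grepl(site_row$ref_seq, window, fixed = TRUE))
  }
  if (nchar(window) < 6L) return(FALSE)
  hits <- scan_mres(
    window, mirna_row,
    seed_match_config(allow_wobble = TRUE, allow_mismatch = TRUE,
                      report_all_types = TRUE)
  )
  if (nrow(hits) == 0L) return(FALSE)
  any(
    site_type_rank(hits$site_type) <= site_type_rank(site_row$site_type) &
      hits$n_wobble + hits$n_mismatch <=
        site_row$n_wobble + site_row$n_mismatch
  )
}

#' Ortholog conservation of one MRE site
#'
#' For each clade species the alignment columns spanning the reference
#' site are extracted, gaps are removed, and the window (with one column
#' of flanking context) is checked for an equal-or-stronger site for the
#' same miRNA (see [filter_config()] `conservation_mode`). The returned
#' fraction is conserved species over species whose window gap fraction is
#' at most `max_gap_fraction`; the reference never enters either count.
#'
#' @param site One-row site tibble (columns `start`, `end`, `site_type`,
#'   `n_wobble`, `n_mismatch`).
#' @param aln An [ortholog_alignment()].
#' @param mirna One-row miRNA tibble for the site's miRNA.
#' @param config A [filter_config()].
#' @return A list with `fraction` (`NA` when no species is assessable),
#'   `n_conserved`, `n_assessable`, `defined`.
#' @export
site_conservation <- function(site, aln, mirna, config = filter_config()) {
  if (site$start < 1L || site$end > length(aln$ref_columns)) {
    abort("site lies outside the ungapped reference coordinates")
  }
  cols <- aln$ref_columns[site$start:site$end]
  # one column of context on each side tolerates gap-induced offsets
  col_lo <- max(1L, min(cols) - 1L)
  col_hi <- min(aln$width, max(cols) + 1L)
  clade <- config$conservation_clade %||% alignment_species(aln)
  clade <- setdiff(intersect(clade, names(aln$sequences)), aln$reference)
  ref_seq <- gsub("-", "", substring(aln$sequences[[aln$reference]],
                                     min(cols), max(cols)), fixed = TRUE)
  site_row <- site
  site_row$ref_seq <- ref_seq
  n_conserved <- 0L
  n_assessable <- 0L
  for (sp in clade) {
    win_core <- substring(aln$sequences[[sp]], min(cols), max(cols))
    gap_frac <- mean(seq_chars(win_core) == "-")
    if (gap_frac > config$max_gap_fraction) next
    n_assessable <- n_assessable + 1L
    win <- gsub("-", "",
                substring(aln$sequences[[sp]], col_lo, col_hi), fixed = TRUE)
    if (nchar(win) > 0L &&
        .window_has_site(win, mirna, site_row, config$conservation_mode)) {
      n_conserved <- n_conserved + 1L
    }
  }
  list(
    fraction = if (n_assessable > 0L) n_conserved / n_assessable else NA_real_,
    n_conserved = n_conserved,
    n_assessable = n_assessable,
    defined = n_assessable > 0L
  )
}

#' Annotate a site table with ortholog conservation
#'
#' @param sites Site tibble from [scan_mres()].
#' @param aln An [ortholog_alignment()].
#' @param mirnas miRNA tibble covering every miRNA in `sites`.
#' @param config A [filter_config()].
#' @return `sites` with an added `conservation` column (`NA` when no
#'   species is assessable; such sites fail the conservation filter).
#' @export
annotate_conservation <- function(sites, aln, mirnas,
                                  config = filter_config()) {
  idx <- match(sites$mirna, mirnas$name)
  if (anyNA(idx)) {
    abort(paste("sites reference miRNAs absent from the miRNA table:",
                paste(unique(sites$mirna[is.na(idx)]), collapse = ", ")))
  }
  sites$conservation <- vapply(seq_len(nrow(sites)), function(i) {
    site_conservation(sites[i, ], aln, mirnas[idx[i], ], config)$fraction
  }, numeric(1))
  sites
}

# Single-linkage collapse of site intervals into unique-MRE groups:
# sites whose footprints overlap by >= min_overlap nt (the shared seed
# core) are merged. Returns an integer group id per site row.
.mre_groups <- function(sites, min_overlap = 6L) {
  if (nrow(sites) == 0L) return(integer())
  ord <- order(sites$start, sites$end)
  group <- integer(nrow(sites))
  cur_group <- 0L
  cur_end <- -Inf
  for (i in ord) {
    # overlap with the growing group = cur_end - start + 1
    if (cur_end - sites$start[i] + 1L >= min_overlap) {
      cur_end <- max(cur_end, sites$end[i])
    } else {
      cur_group <- cur_group + 1L
      cur_end <- sites$end[i]
    }
    group[i] <- cur_group
  }
  group
}

#' Summarize MRE/miRNA redundancy in a candidate set
#'
#' Sites are collapsed into unique MREs by overlapping genomic footprint
#' (single linkage, overlap of at least `min_overlap` nt). Redundancy is
#' counted in both directions: MREs targeted by more than one miRNA, and
#' miRNAs targeting more than one MRE.
#'
#' @param sites Deduplicated site tibble (unique `(mirna, start, site_type)`).
#' @param min_overlap Minimum footprint overlap to merge sites into one MRE.
#' @return A list with `mres_with_multiple_mirnas`,
#'   `mirnas_with_multiple_mres`, `n_unique_mres`, `n_unique_mirnas`, and
#'   `per_mirna` (tibble of miRNA -> MRE group ids).
#' @export
redundancy_summary <- function(sites, min_overlap = 6L) {
  if (nrow(sites) == 0L) {
    return(list(
      mres_with_multiple_mirnas = 0L, mirnas_with_multiple_mres = 0L,
      n_unique_mres = 0L, n_unique_mirnas = 0L,
      per_mirna = tibble(mirna = character(), mre_groups = list())
    ))
  }
  sites$mre_group <- .mre_groups(sites, min_overlap)
  by_group <- sites %>%
    group_by(.data$mre_group) %>%
    summarise(n_mirnas = dplyr::n_distinct(.data$mirna), .groups = "drop")
  per_mirna <- sites %>%
    group_by(.data$mirna) %>%
    summarise(mre_groups = list(sort(unique(.data$mre_group))),
              .groups = "drop")
  list(
    mres_with_multiple_mirnas = sum(by_group$n_mirnas > 1L),
    mirnas_with_multiple_mres = sum(lengths(per_mirna$mre_groups) > 1L),
    n_unique_mres = nrow(by_group),
    n_unique_mirnas = nrow(per_mirna),
    per_mirna = per_mirna
  )
}

#' Apply the hierarchical candidate-selection funnel
#'
#' Stages, in order: (1) the input site universe; (2) drop sites carrying
#' a mismatched pair; (3) drop 6mer sites carrying a G:U wobble; (4) keep
#' sites conserved in at least `conservation_threshold` of assessable
#' clade species (sites with undefined conservation fail); (5) keep sites
#' whose miRNA's species set contains every required species. Surviving
#' sites are then collapsed to unique MREs and unique miRNAs.
#'
#' @param sites Site tibble (from [scan_mres()] or
#'   [read_prediction_table()]); a pre-computed `conservation` column is
#'   used when present, otherwise `aln` must be supplied.
#' @param mirnas miRNA tibble with `species` list column (needed for the
#'   species stage and for conservation scanning); optional when `sites`
#'   carries a `species` list column itself.
#' @param aln Optional [ortholog_alignment()] for stage 4.
#' @param config A [filter_config()].
#' @param reference_counts Optional named numeric vector of externally
#'   published per-stage counts (names among
#'   `universe, no_mismatch, no_6mer_wobble, conserved, required_species`).
#'   Computed counts are compared against them and every discrepancy is
#'   recorded in the report's `notes` -- surfaced, never resolved.
#' @return A list with `sites` (survivors) and `report` (a `funnel_report`).
#' @export
apply_funnel <- function(sites, mirnas = NULL, aln = NULL,
                         config = filter_config(),
                         reference_counts = NULL) {
  stage_names <- c("universe", "no_mismatch", "no_6mer_wobble",
                   "conserved", "required_species")
  stages <- list()
  s <- sites
  stages[["universe"]] <- nrow(s)

  if (config$drop_mismatch) s <- filter(s, .data$n_mismatch == 0L)
  stages[["no_mismatch"]] <- nrow(s)

  if (config$drop_6mer_wobble) {
    s <- filter(s, !(.data$site_type == "6mer" & .data$n_wobble >= 1L))
  }
  stages[["no_6mer_wobble"]] <- nrow(s)

  if (nrow(s) > 0L) {
    if (!"conservation" %in% names(s)) {
      if (is.null(aln)) {
        abort("sites carry no conservation column and no alignment was supplied")
      }
      if (is.null(mirnas)) abort("mirnas are required to compute conservation")
      s <- annotate_conservation(s, aln, mirnas, config)
    }
    s <- filter(s, !is.na(.data$conservation) &
                  .data$conservation >= config$conservation_threshold)
  }
  stages[["conserved"]] <- nrow(s)

  species_of <- function(tbl) {
    if ("species" %in% names(tbl)) return(tbl$species)
    if (is.null(mirnas)) {
      abort("species stage needs a species column on sites or a miRNA table")
    }
    idx <- match(tbl$mirna, mirnas$name)
    if (anyNA(idx)) {
      abort(paste("missing species annotations for miRNAs:",
                  paste(unique(tbl$mirna[is.na(idx)]), collapse = ", ")))
    }
    mirnas$species[idx]
  }
  if (nrow(s) > 0L) {
    sp <- species_of(s)
    keep <- vapply(sp, function(tags) all(config$required_species %in% tags),
                   logical(1))
    s <- s[keep, , drop = FALSE]
  }
  stages[["required_species"]] <- nrow(s)

  red <- redundancy_summary(s)
  notes <- character()
  if (!is.null(reference_counts)) {
    for (nm in intersect(names(reference_counts), stage_names)) {
      for (val in reference_counts[names(reference_counts) == nm]) {
        if (val != stages[[nm]]) {
          notes <- c(notes, sprintf(
            "stage '%s': computed %d, reference reports %s (discrepancy left unresolved)",
            nm, stages[[nm]], format(val)
          ))
        }
      }
    }
  }
  report <- structure(
    list(
      stages = tibble(
        stage = stage_names,
        n_hits = as.integer(unlist(stages[stage_names]))
      ),
      unique_mre_count = red$n_unique_mres,
      unique_mirna_count = red$n_unique_mirnas,
      redundancy = red,
      notes = notes
    ),
    class = "funnel_report"
  )
  list(sites = s, report = report)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-18s %d\n", x$stages$stage[i], x$stages$n_hits[i]))
  }
  cat(sprintf("  unique MREs: %d, unique miRNAs: %d\n",
              x$unique_mre_count, x$unique_mirna_count))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' @rdname apply_funnel
#' @param x A `funnel_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.funnel_report <- function(x, ...) x$stages

#' @rdname apply_funnel
#' @exportS3Method generics::glance
glance.funnel_report <- function(x, ...) {
  tibble(
    n_universe = x$stages$n_hits[1L],
    n_surviving = x$stages$n_hits[nrow(x$stages)],
    unique_mre_count = x$unique_mre_count,
    unique_mirna_count = x$unique_mirna_count,
    mres_with_multiple_mirnas = x$redundancy$mres_with_multiple_mirnas,
    mirnas_with_multiple_mres = x$redundancy$mirnas_with_multiple_mres,
    n_notes = length(x$notes)
  )
}

#' @rdname apply_funnel
#' @param object A `funnel_report`.
#' @exportS3Method ggplot2::autoplot
autoplot.funnel_report <- function(object, ...) {
  df <- object$stages
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n_hits)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_hits), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "surviving predicted hits") +
    ggplot2::theme_minimal()
}
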
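#' Default polyadenylation-signal hexamer variants
#'
#' The canonical AATAAA plus the common single-substitution variants ATTAAA
#' and TATAAA, and the rarer AGTAAA. Coordinates downstream of a stop codon
#' are 1-based with position 1 = first nucleotide after the stop.
#' @export
POLYA_VARIANTS <- c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA")

#' Scan a sequence for polyadenylation-signal hexamers
#'
#' Reports every occurrence (including overlapping ones) of any hexamer
#' variant whose start lies at or before `region_end`. `N` never matches.
#' Matching is case-insensitive and RNA input is accepted (U is read as T).
#'
#' @param seq Nucleotide sequence (string over `{A,C,G,T,N}`, or RNA).
#' @param variants Character vector of hexamer variants to scan for.
#' @param region_end Only report hits starting at or before this 1-based
#'   position (default: whole sequence).
#' @return Tibble with columns `position` (1-based hexamer start), `hexamer`
#'   and `strand` (always `"+"`), sorted by position.
#' @export
#' @examples
#' scan_polya_signals("CCCAATAAACCC")
scan_polya_signals <- function(seq, variants = POLYA_VARIANTS,
                               region_end = NULL) {
  empty <- tibble(position = integer(), hexamer = character(),
                  strand = character())
  if (identical(seq, "")) return(empty)
  seq <- normalize_seq(seq)
  variants <- toupper(chartr("Uu", "Tt", variants))
  if (any(nchar(variants) != 6L)) abort("all variants must be hexamers")
  n <- nchar(seq)
  if (n < 6L) return(empty)
  if (is.null(region_end)) region_end <- n
  if (region_end > n) abort("region_end exceeds sequence length")
  starts <- seq_len(n - 5L)
  windows <- substring(seq, starts, starts + 5L)
  hit <- windows %in% variants & starts <= region_end
  tibble(
    position = starts[hit],
    hexamer = windows[hit],
    strand = "+"
  ) %>% arrange(.data$position)
}

#' U/G fraction of a sequence window
#'
#' Fraction of T (standing for U on the mRNA) plus G bases in the
#' `width`-nt window starting at 1-based `start`.
#'
#' @param seq Nucleotide sequence.
#' @param start 1-based window start.
#' @param width Window width in nt (must be positive).
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' ug_fraction("TGTGTGTGTGTGTGAA", 1, 16) # 0.875
ug_fraction <- function(seq, start, width) {
  if (length(width) != 1L || !is.numeric(width) || is.na(width) || width <= 0) {
    abort("width must be a positive integer")
  }
  seq <- normalize_seq(seq)
  start <- assert_count(start, "start")
  end <- min(start + width - 1L, nchar(seq))
  if (start > nchar(seq)) abort("window start lies outside the sequence")
  bases <- seq_chars(substring(seq, start, end))
  sum(bases %in% c("T", "G")) / width
}

#' Find candidate cleavage sites downstream of a poly(A) signal
#'
#' One candidate is reported for every CA dinucleotide whose C lies within
#' `window` nt downstream of the signal hexamer start (distance measured
#' signal start to the C of CA). Each candidate is annotated with the U/G
#' fraction of the `ug_width`-nt window beginning `ug_offset` nt after the
#' C of the CA; candidates whose U/G window runs past the sequence end are
#' flagged `truncated` (fraction computed over the available bases,
#' denominated by the full width), not dropped.
#'
#' @param seq Nucleotide sequence.
#' @param signal A one-row tibble from [scan_polya_signals()] or a 1-based
#'   signal position.
#' @param window Integer interval `c(min, max)` of allowed distances from
#'   the signal start to the C of CA (default `c(1, 30)`).
#' @param ug_width Width of the downstream U/G window (default 16).
#' @param ug_offset Gap between the C of CA and the U/G window start
#'   (default 17).
#' @return Tibble with columns `ca_position`, `signal_position`,
#'   `distance_from_signal`, `ug_window_start`, `ug_window_width`,
#'   `ug_fraction`, `truncated`.
#' @export
find_cleavage_candidates <- function(seq, signal, window = c(1L, 30L),
                                     ug_width = 16L, ug_offset = 17L) {
  seq <- normalize_seq(seq)
  signal_position <- if (is.data.frame(signal)) {
    as.integer(signal$position[[1L]])
  } else {
    assert_count(signal, "signal position")
  }
  if (length(window) != 2L || window[1L] > window[2L]) {
    abort("window must be an increasing integer interval c(min, max)")
  }
  ug_width <- assert_count(ug_width, "ug_width")
  ug_offset <- assert_count(ug_offset, "ug_offset", min = 0)
  n <- nchar(seq)
  lo <- signal_position + window[1L]
  hi <- min(signal_position + window[2L], n - 1L)
  empty <- tibble(
    ca_position = integer(), signal_position = integer(),
    distance_from_signal = integer(), ug_window_start = integer(),
    ug_window_width = integer(), ug_fraction = double(), truncated = logical()
  )
  if (lo > hi) return(empty)
  pos <- lo:hi
  is_ca <- substring(seq, pos, pos + 1L) == "CA"
  pos <- pos[is_ca]
  if (length(pos) == 0L) return(empty)
  ug_start <- pos + ug_offset
  tibble(
    ca_position = pos,
    signal_position = signal_position,
    distance_from_signal = pos - signal_position,
    ug_window_start = ug_start,
    ug_window_width = ug_width,
    ug_fraction = map_dbl(ug_start, function(s) {
      if (s > n) return(0)
      ug_fraction(seq, s, ug_width)
    }),
    truncated = ug_start + ug_width - 1L > n
  )
}
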
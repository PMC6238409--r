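#' @keywords internal
"_PACKAGE"

#' @import rlang
#' @importFrom dplyr %>% arrange bind_rows count distinct filter group_by
#'   lag left_join mutate n pull rename row_number select summarise ungroup
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_dbl map_int map_lgl map2 pmap imap keep
#' @importFrom stats lm coef qt sd pnorm setNames
#' @importFrom generics tidy glance
NULL

# DNA complement lookup; U is carried as T internally
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Normalize a nucleotide sequence to an internal DNA representation
#'
#' Uppercases, converts U to T (RNA input is transcribed on read), and
#' validates the alphabet. Gaps (`-`) are permitted only when `allow_gap`.
#'
#' @param x Single character string.
#' @param allow_gap Permit the `-` gap character (aligned sequences).
#' @param what Label used in error messages.
#' @return Normalized DNA string over `{A,C,G,T,N}` (plus `-` if allowed).
#' @export
normalize_seq <- function(x, allow_gap = FALSE, what = "sequence") {
  if (length(x) != 1L || !is.character(x) || is.na(x)) {
    abort(sprintf("%s must be a single character string", what))
  }
  out <- toupper(chartr("Uu", "Tt", x))
  alphabet <- c("A", "C", "G", "T", "N", if (allow_gap) "-")
  chars <- strsplit(out, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), alphabet)
  if (length(bad) > 0L) {
    abort(sprintf(
      "%s contains non-nucleotide characters: %s",
      what, paste(bad, collapse = ", ")
    ))
  }
  out
}

# Split a sequence into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

complement_base <- function(b) unname(.COMPLEMENT[b])

#' Reverse complement of a DNA string
#' @param x DNA string over `{A,C,G,T,N}`.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(x) {
  paste(rev(complement_base(seq_chars(normalize_seq(x)))), collapse = "")
}

# Classify one target:miRNA base apposition. Both bases are DNA-normalized;
# the miRNA U appears as T. Returns "wc", "wobble", "mismatch" or "none"
# (sentinel/N positions can never pair).
pair_class <- function(target, mirna) {
  out <- rep("mismatch", length(target))
  out[target == "N" | mirna == "N" | target == "-" | mirna == "-"] <- "none"
  wc <- target == unname(.COMPLEMENT[mirna]) & out != "none"
  out[wc] <- "wc"
  wob <- !wc & out != "none" &
    ((target == "G" & mirna == "T") | (target == "T" & mirna == "G"))
  out[wob] <- "wobble"
  out
}

# Positive scalar integer check
assert_count <- function(x, what, min = 1) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("%s must be a single integer >= %s", what, min))
  }
  as.integer(x)
}
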
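#' Positional-landscape configuration
#'
#' @param half_width Peak half-width: nt on either side of an MRE position
#'   (default 25).
#' @param coop_min,coop_max Cooperative spacing bounds in nt
#'   (defaults 8 and 50; `coop_min < coop_max`).
#' @param spacing_mode `"center"` (default): distance between MRE
#'   positions; `"edge"`: gap between site footprints (`start`/`end`
#'   columns required).
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(half_width = 25L, coop_min = 8L,
                             coop_max = 50L,
                             spacing_mode = c("center", "edge")) {
  half_width <- assert_count(half_width, "half_width")
  if (coop_min >= coop_max) abort("coop_min must be below coop_max")
  structure(
    list(half_width = half_width, coop_min = coop_min, coop_max = coop_max,
         spacing_mode = match.arg(spacing_mode)),
    class = "landscape_config"
  )
}

#' Build the NRQ-weighted positional interaction landscape
#'
#' One peak is drawn per `(miRNA, MRE position)` with height equal to the
#' miRNA's point NRQ, spanning `half_width` nt on either side (clipped to
#' the UTR). The per-position track is the maximum peak height covering
#' each nucleotide (so heights remain interpretable as NRQs); intervals
#' covered by two or more peaks are reported separately as overlaps.
#'
#' @param sites Tibble with columns `mirna`, `position` (MRE position, nt)
#'   and `nrq` (point NRQ, positive).
#' @param utr_length UTR length in nt.
#' @param config A [landscape_config()].
#' @return An object of class `utr_landscape`: `track` (tibble
#'   `position, height`), `peaks` (tibble `mirna, mre_position, start,
#'   end, height`), `overlaps` (tibble `start, end`), `utr_length`,
#'   `config`.
#' @export
build_landscape <- function(sites, utr_length,
                            config = landscape_config()) {
  utr_length <- assert_count(utr_length, "utr_length")
  needed <- c("mirna", "position", "nrq")
  if (!all(needed %in% names(sites))) {
    abort("sites must have columns mirna, position, nrq")
  }
  if (any(sites$position < 1L | sites$position > utr_length)) {
    abort("site position lies outside the UTR")
  }
  if (any(!is.finite(sites$nrq) | sites$nrq <= 0)) {
    abort("every peak needs a positive NRQ")
  }
  peaks <- tibble(
    mirna = sites$mirna,
    mre_position = as.integer(sites$position),
    start = pmax(1L, as.integer(sites$position) - config$half_width),
    end = pmin(utr_length, as.integer(sites$position) + config$half_width),
    height = sites$nrq
  )
  height <- numeric(utr_length)
  coverage <- integer(utr_length)
  for (i in seq_len(nrow(peaks))) {
    span <- peaks$start[i]:peaks$end[i]
    height[span] <- pmax(height[span], peaks$height[i])
    coverage[span] <- coverage[span] + 1L
  }
  overlaps <- .runs_to_intervals(coverage >= 2L)
  structure(
    list(
      track = tibble(position = seq_len(utr_length), height = height),
      peaks = peaks,
      overlaps = overlaps,
      utr_length = utr_length,
      config = config
    ),
    class = "utr_landscape"
  )
}

# TRUE runs of a logical vector as 1-based inclusive intervals
.runs_to_intervals <- function(flag) {
  if (!any(flag)) return(tibble(start = integer(), end = integer()))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(start = starts[r$values], end = ends[r$values])
}

#' @export
print.utr_landscape <- function(x, ...) {
  cat(sprintf(
    "<utr_landscape> %d peaks on a %d-nt UTR; %d overlap interval(s), covered length %d nt\n",
    nrow(x$peaks), x$utr_length, nrow(x$overlaps), sum(x$track$height > 0)
  ))
  invisible(x)
}

# Pairwise spacing and the shared-MRE relation used to veto pairs
.pair_spacing <- function(sites, i, j, mode) {
  if (mode == "center") {
    abs(sites$position[i] - sites$position[j])
  } else {
    s1 <- sites$start[i]; e1 <- sites$end[i]
    s2 <- sites$start[j]; e2 <- sites$end[j]
    max(0L, max(s1, s2) - min(e1, e2) - 1L)
  }
}

#' Detect cooperative site pairs by spacing
#'
#' Returns every unordered pair of sites whose spacing lies within
#' `[coop_min, coop_max]`, excluding pairs of the same miRNA and pairs
#' whose miRNAs share common or overlapping MREs anywhere in the site set
#' (simultaneous binding at shared footprints being impossible). The
#' relation is symmetric and anti-reflexive.
#'
#' @param sites Tibble with `mirna`, `position`, and (for footprint
#'   overlap checks and `spacing_mode = "edge"`) `start`/`end` columns;
#'   sites without footprints are treated as 1-nt points.
#' @param config A [landscape_config()].
#' @return Tibble with one row per pair: `mirna_a, position_a, mirna_b,
#'   position_b, spacing`.
#' @export
cooperative_pairs <- function(sites, config = landscape_config()) {
  empty <- tibble(mirna_a = character(), position_a = integer(),
                  mirna_b = character(), position_b = integer(),
                  spacing = integer())
  n <- nrow(sites)
  if (n < 2L) return(empty)
  if (!"start" %in% names(sites)) sites$start <- as.integer(sites$position)
  if (!"end" %in% names(sites)) sites$end <- as.integer(sites$position)

  # miRNA pairs sharing an overlapping MRE footprint are never cooperative
  sharing <- new.env(parent = emptyenv())
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (sites$mirna[i] == sites$mirna[j]) next
      if (sites$start[j] <= sites$end[i] && sites$start[i] <= sites$end[j]) {
        key <- paste(sort(c(sites$mirna[i], sites$mirna[j])), collapse = "\r")
        assign(key, TRUE, envir = sharing)
      }
    }
  }
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (sites$mirna[i] == sites$mirna[j]) next
      key <- paste(sort(c(sites$mirna[i], sites$mirna[j])), collapse = "\r")
      if (exists(key, envir = sharing, inherits = FALSE)) next
      sp <- .pair_spacing(sites, i, j, config$spacing_mode)
      if (sp >= config$coop_min && sp <= config$coop_max) {
        rows[[length(rows) + 1L]] <- tibble(
          mirna_a = sites$mirna[i], position_a = as.integer(sites$position[i]),
          mirna_b = sites$mirna[j], position_b = as.integer(sites$position[j]),
          spacing = as.integer(sp)
        )
      }
    }
  }
  if (length(rows) == 0L) empty else bind_rows(rows)
}

#' Merge landscape peaks into cluster regions
#'
#' Single-linkage merge of peaks with overlapping intervals into maximal
#' regions. Each region reports its interval (the union of member peak
#' intervals), its members, and whether it contains at least one
#' cooperative pair under the spacing rule.
#'
#' @param landscape A `utr_landscape` from [build_landscape()], or a peak
#'   tibble with `mirna, mre_position, start, end` columns.
#' @param config A [landscape_config()].
#' @return Tibble with one row per region: `region, start, end, n_peaks,
#'   mirnas` (list), `positions` (list), `has_cooperative_pair`.
#' @export
cluster_regions <- function(landscape, config = landscape_config()) {
  peaks <- if (inherits(landscape, "utr_landscape")) {
    landscape$peaks
  } else {
    landscape
  }
  empty <- tibble(region = integer(), start = integer(), end = integer(),
                  n_peaks = integer(), mirnas = list(), positions = list(),
                  has_cooperative_pair = logical())
  if (nrow(peaks) == 0L) return(empty)
  ord <- order(peaks$start, peaks$end)
  peaks <- peaks[ord, , drop = FALSE]
  region <- integer(nrow(peaks))
  cur <- 0L
  cur_end <- -Inf
  for (i in seq_len(nrow(peaks))) {
    if (peaks$start[i] <= cur_end) {
      cur_end <- max(cur_end, peaks$end[i])
    } else {
      cur <- cur + 1L
      cur_end <- peaks$end[i]
    }
    region[i] <- cur
  }
  peaks$region <- region
  peaks %>%
    group_by(.data$region) %>%
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_peaks = n(),
      mirnas = list(unique(.data$mirna)),
      positions = list(.data$mre_position),
      has_cooperative_pair = {
        members <- data.frame(mirna = .data$mirna,
                              position = .data$mre_position)
        nrow(cooperative_pairs(members, config)) > 0L
      },
      .groups = "drop"
    )
}

#' @rdname build_landscape
#' @param object A `utr_landscape`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.utr_landscape <- function(object, ...) {
  p <- ggplot2::ggplot(object$track,
                       ggplot2::aes(x = .data$position, y = .data$height)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::labs(x = "3'UTR position (nt)", y = "NRQ") +
    ggplot2::theme_minimal()
  if (nrow(object$overlaps) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = object$overlaps,
      ggplot2::aes(x = .data$start, xend = .data$end, y = 0, yend = 0),
      colour = "red", linewidth = 2, inherit.aes = FALSE
    )
  }
  p
}
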
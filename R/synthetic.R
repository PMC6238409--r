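# Synthetic-data generators. Every generator is deterministic under a
# fixed seed (withr::with_seed leaves the caller's RNG untouched) and
# emits a planted-truth table sufficient to score downstream stages.

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(n, gc = 0.4) {
  paste(sample(.BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate random mature miRNA records
#'
#' Random 22-nt RNA sequences with pairwise-distinct 6-nt seeds
#' (rejection sampling on the seed).
#'
#' @param n Number of miRNAs (>= 1).
#' @param rng_seed Integer seed.
#' @param species Species tag set given to every miRNA (default
#'   `c("mmu", "hsa")`).
#' @return A miRNA tibble from [mirna_records()], names `syn-miR-1` ...
#' @export
gen_mirnas <- function(n, rng_seed = 1L, species = c("mmu", "hsa")) {
  n <- assert_count(n, "n")
  withr::with_seed(rng_seed, {
    seqs <- character(n)
    seeds <- character(0)
    for (i in seq_len(n)) {
      repeat {
        s <- paste(sample(c("A", "C", "G", "U"), 22L, replace = TRUE),
                   collapse = "")
        seed6 <- substring(s, 2L, 7L)
        if (!seed6 %in% seeds) break
      }
      seqs[i] <- s
      seeds <- c(seeds, substring(s, 2L, 7L))
    }
    mirna_records(paste0("syn-miR-", seq_len(n)), seqs,
                  species = rep(list(species), n))
  })
}

# Target-site string for one (miRNA, type): the perfect Watson-Crick
# match, 5'->3' on the mRNA. pairing_idx maps each site string position
# to the opposed miRNA nucleotide (NA at the A1 position).
.site_template <- function(mirna_seq, type) {
  m <- seq_chars(normalize_seq(mirna_seq, what = "miRNA sequence"))
  core <- rev(complement_base(m[2:7])) # opposes miRNA nt 7..2
  core_idx <- 7:2
  switch(type,
    "6mer" = list(chars = core, mirna_idx = core_idx),
    "7mer-A1" = list(chars = c(core, "A"), mirna_idx = c(core_idx, NA)),
    "7mer-m8" = list(chars = c(complement_base(m[8L]), core),
                     mirna_idx = c(8L, core_idx)),
    "8mer" = list(chars = c(complement_base(m[8L]), core, "A"),
                  mirna_idx = c(8L, core_idx, NA)),
    abort(sprintf("unknown site type '%s'", type))
  )
}

# Apply wobble/mismatch edits to a site template. Edits are restricted to
# seed-core positions (opposing miRNA nt 2-7) so no canonical sub-site
# survives at the edited register.
.edit_site <- function(tmpl, mirna_seq, n_wobble, n_mismatch) {
  m <- seq_chars(normalize_seq(mirna_seq, what = "miRNA sequence"))
  core_pos <- which(!is.na(tmpl$mirna_idx) & tmpl$mirna_idx %in% 2:7)
  used <- integer()
  if (n_wobble > 0L) {
    eligible <- core_pos[m[tmpl$mirna_idx[core_pos]] %in% c("G", "T")]
    if (length(eligible) < n_wobble) {
      abort("infeasible plant: miRNA seed has no G/U position for a wobble edit")
    }
    for (p in sample(rep(eligible, 2L))[seq_len(n_wobble)]) {
      b <- m[tmpl$mirna_idx[p]]
      tmpl$chars[p] <- if (b == "G") "T" else "G"
      used <- c(used, p)
    }
  }
  if (n_mismatch > 0L) {
    eligible <- setdiff(core_pos, used)
    if (length(eligible) < n_mismatch) abort("infeasible plant: no free core position")
    for (p in sample(rep(eligible, 2L))[seq_len(n_mismatch)]) {
      b <- m[tmpl$mirna_idx[p]]
      forbidden <- c(complement_base(b),
                     if (b == "G") "T" else if (b == "T") "G")
      tmpl$chars[p] <- sample(setdiff(.BASES, forbidden), 1L)
    }
  }
  tmpl
}

#' Generate a UTR with planted MREs and a ground-truth table
#'
#' The background is rejection-sampled so that, outside the planted
#' footprints, no spurious canonical site exists for any of the supplied
#' miRNAs: after planting, a canonical strongest-only scan must recover
#' exactly the canonical planted truth. Guard bases flanking each planted
#' site prevent chance upgrades (an adventitious m8 match or A1 adenine).
#' Wobble/mismatch edits are written into the seed core, so edited sites
#' are recovered only under the matching relaxed scan configuration.
#'
#' @param length UTR length in nt.
#' @param spec Tibble with columns `mirna` (index into `mirnas`),
#'   `position` (1-based site start), `site_type`, and optionally
#'   `n_wobble`, `n_mismatch` (defaults 0).
#' @param mirnas miRNA tibble (e.g. from [gen_mirnas()]).
#' @param rng_seed Integer seed.
#' @param gc Background GC content (default 0.4).
#' @param allow_overlap Permit overlapping planted footprints (no
#'   recovery guarantee for overlapped sites).
#' @param max_tries Rejection-sampling attempts before giving up.
#' @return A list: `utr` (string) and `truth` (tibble `mirna, start, end,
#'   site_type, n_wobble, n_mismatch, canonical`).
#' @export
gen_utr_with_planted_sites <- function(length, spec, mirnas, rng_seed = 1L,
                                       gc = 0.4, allow_overlap = FALSE,
                                       max_tries = 200L) {
  length <- assert_count(length, "length")
  if (!"n_wobble" %in% names(spec)) spec$n_wobble <- 0L
  if (!"n_mismatch" %in% names(spec)) spec$n_mismatch <- 0L
  withr::with_seed(rng_seed, {
    planted <- vector("list", nrow(spec))
    for (i in seq_len(nrow(spec))) {
      mi <- spec$mirna[[i]]
      row <- if (is.numeric(mi)) mirnas[mi, ] else
        mirnas[match(mi, mirnas$name), ]
      if (nrow(row) == 0L || is.na(row$name)) abort("unknown miRNA in plant spec")
      tmpl <- .site_template(row$sequence, spec$site_type[[i]])
      tmpl <- .edit_site(tmpl, row$sequence, spec$n_wobble[[i]],
                         spec$n_mismatch[[i]])
      start <- as.integer(spec$position[[i]])
      end <- start + length(tmpl$chars) - 1L
      if (start < 1L || end > length) abort("planted footprint does not fit the UTR")
      planted[[i]] <- list(
        mirna = row$name, mirna_seq = row$sequence, start = start, end = end,
        chars = tmpl$chars, type = spec$site_type[[i]],
        n_wobble = as.integer(spec$n_wobble[[i]]),
        n_mismatch = as.integer(spec$n_mismatch[[i]])
      )
    }
    if (!allow_overlap && nrow(spec) > 1L) {
      ivs <- tibble(
        start = map_int(planted, "start"),
        end = map_int(planted, "end")
      ) %>% arrange(.data$start)
      if (any(ivs$start[-1L] <= ivs$end[-nrow(ivs)])) {
        abort("planted footprints overlap; set allow_overlap = TRUE to permit")
      }
    }
    truth <- tibble(
      mirna = map_chr(planted, "mirna"),
      start = map_int(planted, "start"),
      end = map_int(planted, "end"),
      site_type = map_chr(planted, "type"),
      n_wobble = map_int(planted, "n_wobble"),
      n_mismatch = map_int(planted, "n_mismatch")
    ) %>% mutate(canonical = .data$n_wobble == 0L & .data$n_mismatch == 0L) %>%
      arrange(.data$start, .data$mirna, site_type_rank(.data$site_type))
    canonical_truth <- filter(truth, .data$canonical)
    scan_cfg <- seed_match_config() # canonical, strongest-only

    for (try in seq_len(max_tries)) {
      chars <- seq_chars(.random_dna(length, gc))
      for (p in planted) {
        chars[p$start:p$end] <- p$chars
      }
      # guard bases: block chance m8 extension and A1 adenine upgrades
      for (p in planted) {
        m <- seq_chars(normalize_seq(p$mirna_seq, what = "miRNA"))
        if (p$type %in% c("6mer", "7mer-A1") && p$start > 1L) {
          forbidden <- c(complement_base(m[8L]),
                         if (m[8L] == "G") "T" else if (m[8L] == "T") "G")
          if (chars[p$start - 1L] %in% forbidden) {
            chars[p$start - 1L] <- setdiff(.BASES, forbidden)[1L]
          }
        }
        if (p$type %in% c("6mer", "7mer-m8") && p$end < length) {
          if (chars[p$end + 1L] == "A") chars[p$end + 1L] <- "C"
        }
      }
      utr <- paste(chars, collapse = "")
      hits <- scan_mres(utr, mirnas, scan_cfg)
      if (identical(
        paste(hits$mirna, hits$start, hits$site_type),
        paste(canonical_truth$mirna, canonical_truth$start,
              canonical_truth$site_type)
      )) {
        return(list(utr = utr, truth = truth))
      }
    }
    abort("could not sample a clean background; spec may be infeasible")
  })
}

#' Generate an ortholog alignment with per-species site retention
#'
#' Each non-reference species is derived from the reference UTR: every
#' planted site is retained with the species' conservation probability or
#' disrupted by a single seed-core substitution that breaks pairing;
#' background positions (outside planted footprints) accumulate random
#' substitutions and gap characters. No insertions are made, so ungapping
#' the reference reproduces the input UTR.
#'
#' @param utr Reference UTR string.
#' @param truth Planted-truth tibble from [gen_utr_with_planted_sites()].
#' @param mirnas miRNA tibble covering the truth's miRNAs.
#' @param n_species Number of non-reference ortholog species.
#' @param conservation_probs Per-species site-retention probability
#'   (scalar or length `n_species`).
#' @param rng_seed Integer seed.
#' @param reference Reference species name (default `"mmu"`).
#' @param background_sub_rate Background substitution probability per nt.
#' @param gap_rate Background gap probability per nt.
#' @return A list: `alignment` (an [ortholog_alignment()]) and
#'   `retention` (tibble `species, mirna, start, retained`).
#' @export
gen_ortholog_alignment <- function(utr, truth, mirnas, n_species,
                                   conservation_probs = 0.9,
                                   rng_seed = 1L, reference = "mmu",
                                   background_sub_rate = 0.02,
                                   gap_rate = 0.01) {
  n_species <- assert_count(n_species, "n_species")
  probs <- rep_len(conservation_probs, n_species)
  if (any(probs < 0 | probs > 1)) abort("conservation probabilities must be in [0, 1]")
  ref_chars <- seq_chars(normalize_seq(utr, what = "utr"))
  n <- length(ref_chars)
  in_site <- rep(FALSE, n)
  for (i in seq_len(nrow(truth))) {
    in_site[truth$start[i]:truth$end[i]] <- TRUE
  }
  withr::with_seed(rng_seed, {
    seqs <- list()
    seqs[[reference]] <- utr
    retention <- list()
    for (s in seq_len(n_species)) {
      sp <- sprintf("sp%02d", s)
      chars <- ref_chars
      kept <- logical(nrow(truth))
      for (i in seq_len(nrow(truth))) {
        kept[i] <- stats::runif(1) < probs[s]
        if (!kept[i]) {
          row <- mirnas[match(truth$mirna[i], mirnas$name), ]
          tmpl <- .site_template(row$sequence, truth$site_type[i])
          core_pos <- which(!is.na(tmpl$mirna_idx) & tmpl$mirna_idx %in% 2:7)
          p <- sample(rep(core_pos, 2L), 1L)
          m <- seq_chars(normalize_seq(row$sequence, what = "miRNA"))
          b <- m[tmpl$mirna_idx[p]]
          forbidden <- c(complement_base(b),
                         if (b == "G") "T" else if (b == "T") "G")
          chars[truth$start[i] + p - 1L] <-
            sample(setdiff(.BASES, c(forbidden, chars[truth$start[i] + p - 1L])), 1L)
        }
      }
      bg <- which(!in_site)
      subs <- bg[stats::runif(length(bg)) < background_sub_rate]
      for (p in subs) chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
      gaps <- bg[stats::runif(length(bg)) < gap_rate]
      chars[gaps] <- "-"
      seqs[[sp]] <- paste(chars, collapse = "")
      retention[[sp]] <- tibble(
        species = sp, mirna = truth$mirna, start = truth$start,
        retained = kept
      )
    }
    list(
      alignment = ortholog_alignment(unlist(seqs), reference = reference),
      retention = bind_rows(retention)
    )
  })
}

#' Ct-experiment simulation specification
#'
#' @param mirnas Character vector of miRNA assay names.
#' @param enrichment True fold enrichment of each miRNA in the test
#'   pull-down over the control (recycled; > 0).
#' @param lysate_rel_abundance Lysate abundance of each miRNA relative to
#'   the reference assay (recycled; > 0).
#' @param e_bait,e_taqman Assay efficiencies used to convert abundance to
#'   cycles.
#' @param baseline_ct Control-pulldown miRNA Ct at unit abundance.
#' @param bait_ct Bait Ct in both pull-downs.
#' @param u6_ct Reference (U6) Ct in lysate.
#' @param noise_sd Replicate Ct noise standard deviation (>= 0).
#' @param dropout_ct Computed Cts at or above this value are emitted as
#'   undetermined (`NA`).
#' @param pulldown_replicates,profiling_replicates Replicate counts.
#' @param no_rt_offset Cycles added to each +RT Ct to form the minus-RT
#'   well.
#' @return A list of class `ct_sim_spec`.
#' @export
ct_sim_spec <- function(mirnas, enrichment = 4,
                        lysate_rel_abundance = 0.01,
                        e_bait = 1.952, e_taqman = 2,
                        baseline_ct = 28, bait_ct = 20, u6_ct = 18,
                        noise_sd = 0, dropout_ct = 40,
                        pulldown_replicates = 4L,
                        profiling_replicates = 3L,
                        no_rt_offset = 12) {
  enrichment <- rep_len(enrichment, length(mirnas))
  lysate_rel_abundance <- rep_len(lysate_rel_abundance, length(mirnas))
  if (any(enrichment <= 0)) abort("enrichments must be positive")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  structure(
    list(mirnas = mirnas, enrichment = enrichment,
         lysate_rel_abundance = lysate_rel_abundance,
         e_bait = e_bait, e_taqman = e_taqman, baseline_ct = baseline_ct,
         bait_ct = bait_ct, u6_ct = u6_ct, noise_sd = noise_sd,
         dropout_ct = dropout_ct,
         pulldown_replicates = as.integer(pulldown_replicates),
         profiling_replicates = as.integer(profiling_replicates),
         no_rt_offset = no_rt_offset),
    class = "ct_sim_spec"
  )
}

#' Simulate a qPCR plate table from known enrichments
#'
#' Cts are drawn as `baseline - log(abundance)/log(efficiency) +
#' Normal(0, sd)` under the pull-down contrast structure (test vs control
#' pull-downs with a bait assay, a lysate condition with the reference
#' assay, and matched minus-RT wells). With zero noise the pipeline NRQ
#' equals the configured enrichment exactly. Cts at or above `dropout_ct`
#' are emitted as undetermined (`NA`).
#'
#' @param spec A [ct_sim_spec()].
#' @param rng_seed Integer seed.
#' @return A plate tibble (`sample, assay, condition, replicate, ct,
#'   rt_control`).
#' @export
gen_ct_experiment <- function(spec, rng_seed = 1L) {
  if (!inherits(spec, "ct_sim_spec")) abort("spec must be a ct_sim_spec")
  withr::with_seed(rng_seed, {
    noise <- function(k) stats::rnorm(k, 0, spec$noise_sd)
    rows <- list()
    add <- function(sample, assay, condition, replicate, ct) {
      ct[!is.na(ct) & ct >= spec$dropout_ct] <- NA_real_
      rows[[length(rows) + 1L]] <<- tibble(
        sample = sample, assay = assay, condition = condition,
        replicate = as.integer(replicate), ct = ct, rt_control = FALSE
      )
    }
    for (r in seq_len(spec$pulldown_replicates)) {
      for (cond in c("wt_utr", "control_utr")) {
        smp <- paste0(cond, "_", r)
        add(smp, "GFP", cond, r, spec$bait_ct + noise(1))
        for (i in seq_along(spec$mirnas)) {
          abund <- if (cond == "wt_utr") spec$enrichment[i] else 1
          ct <- spec$baseline_ct - log(abund) / log(spec$e_taqman) + noise(1)
          add(smp, spec$mirnas[i], cond, r, ct)
        }
      }
    }
    for (r in seq_len(spec$profiling_replicates)) {
      smp <- paste0("lysate_", r)
      add(smp, "U6", "lysate", r, spec$u6_ct + noise(1))
      for (i in seq_along(spec$mirnas)) {
        ct <- spec$u6_ct - log2(spec$lysate_rel_abundance[i]) + noise(1)
        add(smp, spec$mirnas[i], "lysate", r, ct)
      }
    }
    plus <- bind_rows(rows)
    minus <- plus
    minus$ct <- ifelse(is.na(plus$ct), NA_real_, plus$ct + spec$no_rt_offset)
    minus$ct[!is.na(minus$ct) & minus$ct >= spec$dropout_ct] <- NA_real_
    minus$rt_control <- TRUE
    bind_rows(plus, minus)
  })
}

#' Simulate a dilution-series standard curve
#'
#' Ten-fold series with `Ct_k = c0 + k / log10(efficiency)` plus optional
#' noise, so [estimate_efficiency()] round-trips the configured
#' efficiency exactly at zero noise.
#'
#' @param efficiency True amplification efficiency (fold per cycle).
#' @param n_points Number of dilution points (default 5).
#' @param c0 Ct of the undiluted sample (default 20).
#' @param noise_sd Ct noise standard deviation (default 0).
#' @param rng_seed Integer seed.
#' @return Tibble `fold_dilution, ct`.
#' @export
gen_dilution_series <- function(efficiency, n_points = 5L, c0 = 20,
                                noise_sd = 0, rng_seed = 1L) {
  n_points <- assert_count(n_points, "n_points", min = 3)
  if (efficiency <= 1) abort("efficiency must exceed 1")
  withr::with_seed(rng_seed, {
    k <- 0:(n_points - 1L)
    tibble(
      fold_dilution = 10^k,
      ct = c0 + k / log10(efficiency) + stats::rnorm(n_points, 0, noise_sd)
    )
  })
}
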
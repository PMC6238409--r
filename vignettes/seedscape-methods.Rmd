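---
title: "Mapping a 3'UTR miRNA regulatory landscape with seedscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a 3'UTR miRNA regulatory landscape with seedscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscape)
library(dplyr)
```

seedscape implements a complete computational workflow for characterizing
how microRNAs regulate a single 3' untranslated region: where the
transcript ends (polyadenylation-signal and cleavage-site annotation),
where miRNAs can bind (exhaustive seed-match enumeration and
classification), which candidate sites are worth pursuing (a hierarchical
conservation funnel), whether candidate miRNAs physically associate with
the UTR (efficiency-corrected qPCR quantification of RNA pull-downs), and
how interacting sites are arranged (a positional landscape with
cooperative-spacing cluster calls). The motivating application is the
mouse *Pax6* 3'UTR in pancreatic alpha cells, but every operation takes
generic inputs.

This vignette explains the models and conventions behind each stage, the
parameters that matter, and the design choices made where the underlying
procedures were open to interpretation.

## Transcript 3'-end annotation

`scan_polya_signals()` reports every occurrence of a configurable hexamer
set (default `AATAAA`, `ATTAAA`, `TATAAA`, `AGTAAA`) in a sense-strand
sequence. Coordinates are 1-based with position 1 the first nucleotide
after the stop codon, because that is the convention in which published
signal positions for this locus are quoted. Overlapping hits are all
reported; `N` never matches; case and RNA/DNA alphabet are normalized on
input.

`find_cleavage_candidates()` then looks downstream of one signal for CA
dinucleotides, the preferred cleavage dinucleotide, and annotates each
with the U/G fraction of a 16-nt window beginning 17 nt after the CA —
the composition signature of the downstream U/G-rich element bound by
cleavage-stimulation factor. The textbook expectation places the CA
15–30 nt downstream of the hexamer, but the empirically supported
cleavage site at this locus sits only ~9 nt downstream of its signal, so
the search window is configurable and defaults to the permissive
`[1, 30]` nt, with distance measured from the hexamer start to the C of
the CA. Candidates whose U/G window runs past the end of the sequence are
flagged as truncated rather than dropped, with the fraction denominated
by the full window width.

## Seed-match enumeration and site taxonomy

A miRNA recognizes its target principally through the seed, miRNA
nucleotides 2–7. `scan_mres()` enumerates the four canonical site types:

* **6mer** — a perfect antiparallel match to nucleotides 2–7;
* **7mer-m8** — the 6mer core extended by pairing at miRNA position 8;
* **7mer-A1** — the core plus an adenine in the target across from
  miRNA position 1;
* **8mer** — both extensions.

Three conventions fix the arithmetic:

* The A1 rule requires target adenine regardless of the miRNA's own
  first nucleotide (Argonaute reads the A directly). The A1 position is
  not a pairing position and can carry neither wobble nor mismatch.
* A G:U wobble is target G against miRNA U or target U against miRNA G
  at one pairing position; a mismatch is any other non-Watson-Crick
  apposition. `seed_match_config()` allows at most one of each, so the
  most relaxed universe contains sites with one wobble *and* one
  mismatch, matching how exhaustive prediction tools enumerate.
* Site start is the 5'-most target nucleotide of the match. For
  8mer/7mer-m8 that is the nucleotide opposite miRNA position 8; for
  7mer-A1/6mer it is the seed-core start, with the A1 adenine at the
  site's 3' end. Published positions for 7mer-A1 sites at this locus are
  consistent with this convention (the known miR-375 7mer-A1 site is
  recovered at its printed position from the local sequence
  reconstructed around the mutagenesis primer).

Under strongest-only reporting the precedence is
8mer > 7mer-m8 > 7mer-A1 > 6mer, which is a strict order, so ties cannot
occur; with `report_all_types = TRUE` every satisfiable type at a
register is emitted, giving the "unique hit" universe keyed by
`(miRNA, start, type)`. Identical sites recognized by different miRNAs
sharing a seed are deliberately distinct hits. Offset-6mer, 6mer-alpha,
G-bulge and 3'-supplementary sites are out of scope, as is any
thermodynamic accessibility scoring: the scanner reproduces seed-match
combinatorics, not free energies.

The implementation is validated against an independent brute-force
oracle that tests every (position, type, edit-assignment) combination on
hundreds of random instances; the two agree exactly.

## The candidate funnel

`apply_funnel()` reduces a site universe through ordered stages:
(1) the input universe; (2) remove sites containing a mismatch (rarely
functional, rarely conserved); (3) remove 6mer sites containing a G:U
wobble (wobbles are tolerated by 7/8mers but inactivate the minimal
site); (4) keep sites conserved in at least 85% (configurable) of
assessable clade orthologs; (5) keep sites whose miRNA occurs in a
required species set (default: present in human). Surviving sites are
collapsed to unique MREs (footprints overlapping by at least 6 nt, the
shared seed core, merge by single linkage) and unique miRNAs;
`redundancy_summary()` counts MREs hit by several miRNAs and miRNAs with
several MREs.

Conservation needed an operational definition, since "conserved" is
rarely defined precisely in target-site work. For each non-reference
clade species, the alignment columns spanning the reference site (plus
one column of context to absorb gap-induced offsets) are extracted and
gap-stripped; the species counts as conserving the site when that window
contains a site for the same miRNA of equal-or-stronger type carrying no
more total edits than the reference site. Species whose window exceeds
`max_gap_fraction` (default 0.5) gaps are removed from the denominator;
a site with an empty denominator has undefined conservation and fails
the filter explicitly. A strict mode
(`conservation_mode = "identity"`) instead requires the exact reference
site sequence, for users who prefer sequence identity over functional
equivalence.

`apply_funnel(reference_counts=)` accepts externally published per-stage
counts and records every disagreement between computed and published
values in the report's notes. This is intentional: published stage
counts sometimes disagree between a figure and the accompanying text by
a single hit, and the report surfaces such discrepancies rather than
silently adopting either value.

## qPCR quantification and interaction classification

The quantification stage implements the standard efficiency-corrected
arithmetic:

* `estimate_efficiency()` — least-squares fit of Ct against
  log10(fold dilution); efficiency $E = 10^{1/\text{slope}}$. A slope of
  3.4426 cycles per decade gives $E = 1.952$, the measured bait-primer
  efficiency used as the package default; perfect doubling corresponds
  to $1/\log_{10} 2 \approx 3.3219$. Fits with $r^2 < 0.99$ warn but do
  not error.
* `relative_expression()` — $2^{\Delta Ct}$ with
  $\Delta Ct = Ct_{\text{ref}} - Ct_{\text{target}}$, e.g. a miRNA
  relative to U6 snRNA, also expressed as percent of the reference.
* `fold_difference()` — $E^{\Delta Ct}$ for a single assay between two
  conditions.
* `pfaffl_nrq()` — the Pfaffl normalized relative quantity
  $E_{\text{miRNA}}^{\Delta Ct_{\text{miRNA}}} /
   E_{\text{bait}}^{\Delta Ct_{\text{bait}}}$, with the miRNA assay
  assumed to double per cycle ($E = 2$) and the bait at its measured
  efficiency. With both efficiencies at 2 this reduces to the classic
  $2^{\Delta\Delta Ct}$.
* `mitrap_ratio()` — pull-down relative abundance
  $E_{\text{bait}}^{\overline{Ct}_{\text{bait}}} /
   E_{\text{miRNA}}^{\overline{Ct}_{\text{miRNA}}}$ divided by lysate
  relative abundance, so enrichment is judged independently of cellular
  expression level.

`qc_filter()` applies the plate-level rules in order: samples whose
no-RT margin $Ct_{-RT} - Ct_{+RT}$ falls below 10 cycles are excluded
(an undetermined no-RT well passes — no signal without reverse
transcription is the desired outcome); technical-replicate groups with
Ct standard deviation above 0.5 are discarded; a target is *detected*
only when Ct < 40 in every required replicate; and, only in the control
pull-down, an undetermined Ct is set to 40 when the target was detected
in all test pull-downs (leaving it undefined would discard exactly the
strongest enrichments). Every discarded well carries its rule tag, the
rules partition the discards, and the filter is idempotent.

`classify_interaction()` summarizes four pull-down replicates per miRNA:
the point NRQ is the geometric mean (expression summaries in this
workflow are geometric), and the 95% CI is a t interval on log2 NRQs,
back-transformed. The originating analysis used a commercial package
whose interval math is not documented; the log-t interval is this
package's documented stand-in and is validated by simulation (at n = 4
and replicate noise SD 0.3 cycles it covers the true enrichment in over
90% of runs). Categories: *no interaction* when undetected in any test
pull-down; otherwise *non-specific* when NRQ ≤ 1 (threshold
configurable), *high confidence* when NRQ > 1 with CI lower bound above
1, *low confidence* when NRQ > 1 but the CI reaches below 1.
`classification_summary()` reports counts and percentages over the four
categories, always summing to 100%.

`mann_whitney_exact()` provides the small-sample test used for pull-down
contrasts: the exact two-sided p-value (twice the smaller tail, capped
at 1) by full enumeration of rank assignments for pooled sizes up to 12
— complete separation at 5 vs 5 gives $2/\binom{10}{5} = 0.0079$ — with
midranks for ties and a tie- and continuity-corrected normal
approximation, flagged as approximate, above that. Whether such p-values
should be one- or two-sided is sometimes unstated in published figure
captions; the implementation reports two-sided by default and the
one-sided tails are recoverable from the returned object.

## The positional landscape

`build_landscape()` draws one peak per (miRNA, MRE position) with height
equal to the miRNA's point NRQ and a 25-nt half-width on either side,
clipped to the UTR. The per-position track composites peaks by maximum,
not sum, so track heights remain interpretable as NRQs; intervals
covered by two or more peaks are reported separately as overlaps.
`cooperative_pairs()` returns site pairs spaced 8–50 nt apart — the
range over which simultaneously bound miRNAs act synergistically —
measured center-to-center by default (the published spacing rule does
not define its endpoints; an edge-gap mode is provided). Pairs of the
same miRNA, and pairs of miRNAs that share common or overlapping MREs
anywhere in the set, are excluded: species competing for the same
footprint cannot bind simultaneously. `cluster_regions()` merges
overlapping peak intervals by single linkage into maximal regions and
flags regions containing at least one cooperative pair. Cluster count is
non-increasing in the half-width, and pair detection matches a
brute-force all-pairs oracle exactly.

## Synthetic data: what it emulates and what it does not

The generators produce every input class the pipeline consumes, each
with a recorded ground truth:

* `gen_mirnas()` — random 22-nt mature sequences with pairwise-distinct
  seeds.
* `gen_utr_with_planted_sites()` — a background sequence
  rejection-sampled until a canonical strongest-only scan recovers
  exactly the planted canonical truth, with guard bases flanking each
  site so chance m8/A1 extensions cannot upgrade a planted type.
  Rejection rather than masking is used so the negative space is
  genuinely clean — which also means synthetic UTRs are not
  uniform-random sequence. Wobble/mismatch edits are written into the
  seed core, so edited sites are invisible to stricter configurations.
* `gen_ortholog_alignment()` — per-species site retention with
  configured probability (disruption = one core substitution that
  breaks pairing), background substitutions and gap columns, no
  insertions (so reference coordinates are alignment columns); realized
  retention is recorded per species and site.
* `gen_ct_experiment()` — Cts as
  $\text{baseline} - \log(\text{abundance})/\log(E) +
   \mathcal{N}(0, \sigma)$ under the full contrast structure (test and
  control pull-downs with a bait assay, lysate with U6, matched minus-RT
  wells 12 cycles up), with dropout to undetermined at Ct ≥ 40. At zero
  noise the pipeline NRQ inverts to the configured enrichment exactly.
* `gen_dilution_series()` — $Ct_k = c_0 + k/\log_{10} E$, so the
  efficiency estimator round-trips exactly.

Defaults mirror the study conditions: four pull-down replicates, three
profiling replicates, bait efficiency 1.952, TaqMan efficiency 2,
detection threshold Ct 40, no-RT margin 10, replicate SD cap 0.5,
conservation threshold 0.85, peak half-width 25 nt, cooperative band
8–50 nt. Replicate noise of 0.3 cycles is used in simulation tests as a
realistic TaqMan technical scatter.

What passing tests on these inputs shows is that the arithmetic and the
bookkeeping are right: sites planted are found, enrichments configured
are recovered, filters remove exactly what they claim. What it cannot
show is robustness to the things real data add: sequence composition
bias, secondary structure limiting site accessibility, phylogenetically
correlated conservation (each synthetic species is independent, unlike a
real clade), pipetting-correlated rather than independent Ct noise, and
amplification artefacts. Conclusions about any real UTR still require
the real inputs.

## Numerical choices and problem sizes

Coordinates are 1-based inclusive throughout the API; BED/bedGraph
writers convert to 0-based half-open on output. RNA is transcribed to an
internal DNA alphabet on read; `N` never pairs or matches. Undetermined
Cts are `NA` end to end and propagate (never coerced to zero), except
under the explicit control-side substitution rule. Rank-sum tail
comparisons use an epsilon of 1e-9 to keep midrank arithmetic exact in
floating point. Oracle-equivalence tests run 200 random instances on
30–70-nt UTRs with 2 miRNAs each; CI-coverage simulations use 500
replicate experiments; conservation calibration uses 20 species by 200
replicates. These sizes make the full suite run in a few minutes while
leaving each stochastic check well-powered.

## Known limitations

Alignment-based orthology mapping of poly(A) signals, multiz alignment
construction, thermodynamic site scoring, multi-reference-gene
normalization and multiple-testing correction across miRNAs are out of
scope. The funnel's conservation definition is a package choice (see
above) and, on real alignments, will not numerically reproduce counts
derived with a different unstated definition; the `reference_counts`
mechanism exists to make such differences visible. The landscape treats
every retained MRE of an interacting miRNA as a peak at that miRNA's
single point NRQ; site-level binding contributions are not resolved by
the underlying pull-down assay.
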
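Package: seedscape
Title: miRNA Recognition Element Mapping and miTRAP Quantification for 3'UTRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the miRNA regulatory landscape of a 3'
    untranslated region. Annotates candidate polyadenylation signals and
    cleavage-site features, exhaustively enumerates and classifies miRNA
    recognition elements (6mer, 7mer-A1, 7mer-m8, 8mer seed matches with
    optional G:U wobble and single-mismatch relaxation), applies a
    hierarchical ortholog-conservation candidate funnel, implements
    efficiency-corrected qPCR quantification (standard-curve efficiency,
    delta-Ct expression, Pfaffl normalized relative quantities, miTRAP
    enrichment ratios, exact Mann-Whitney tests) with interaction
    classification, and builds positional cooperative-regulation
    landscapes with spacing-based cluster calls. Includes synthetic-data
    generators with planted ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
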
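Package: cdnassr
Title: Mining, Mapping and Validating Microsatellite Markers in cDNA Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-styled toolkit for genic microsatellite (SSR) marker
    development from cDNA/EST collections. Detects maximal mono- to
    hexanucleotide repeat runs above a length threshold and labels each by its
    fundamental period, classifies runs as perfect or imperfect by total
    length, and reproduces the standard descriptive tables (per-type and
    per-motif frequencies, repeat-number distributions, per-cDNA multiplicity,
    corpus incidence). Downstream stages locate repeats relative to the
    longest open reading frame, anchor cDNAs on a genome, design flanking
    primers and predict amplicons by in-silico PCR for physical mapping,
    score marker polymorphism from accession genotype tables with two-sided
    heatmap clustering, and run hypergeometric over-representation tests with
    Benjamini-Hochberg adjustment. A synthetic-data module generates cDNA
    corpora with planted repeats, genomes, genotype matrices and annotations
    with known truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
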
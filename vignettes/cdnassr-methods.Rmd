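---
title: "Methods: mining, mapping and validating cDNA-SSR markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining, mapping and validating cDNA-SSR markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdnassr)
```

`cdnassr` turns a cDNA/EST collection into a validated genic microsatellite
(SSR) marker panel: it mines repeats, reproduces the standard survey tables,
locates repeats relative to the longest open reading frame, designs flanking
primers and maps them onto a genome by in-silico PCR, scores marker
polymorphism on accession panels with two-sided heatmap clustering, and runs
a hypergeometric over-representation test on gene annotations. This vignette
documents the model behind each stage, the tunable parameters, the numerical
conventions, and what the synthetic-data module does and does not emulate.

## The repeat model

A microsatellite here is a *maximal tandem repeat run* whose fundamental
(smallest) period is 1 to 6 nt and whose full-period length reaches the
detection threshold (`min_len`, default 18 nt). Three conventions pin down
every coordinate:

* **Fundamental-period labelling.** A run such as `(AT)9` also matches
  dictionaries of `ATAT` and `ATATAT`. Each run is labelled by its smallest
  period only, which keeps the per-type totals a partition of the records
  (their sum is the total SSR count, with no double counting). A motif whose
  smallest period is its own length is called *primitive*; there are 4, 12,
  60, 240, 1020 and 4020 primitive motifs of length 1–6. For runs at least
  18 nt long the two notions coincide: a run whose start motif is primitive
  cannot secretly have a smaller period (by the Fine–Wilf periodicity
  argument, a shorter period would have to divide the motif length and would
  make the motif non-primitive).
* **Whole repeat numbers.** A trailing partial motif copy (e.g. the lone `T`
  after `(TC)9`) is excluded from the record's interval, so
  `length = motif_len * repeat_count` exactly. The record's phase is the run
  as it starts (`CT` if the tract begins on `C`); the lexicographically
  minimal rotation is stored alongside (`motif_class`) so summaries can group
  rotations. Reverse complements are never merged: `TC` and `AG` stay
  separate rows, matching how such survey tables are printed.
* **Maximality.** The base before a run and the base after its untrimmed end
  break the periodicity (the synthetic generator enforces this with guard
  bases). Overlapping runs of different periods are both reported; a run
  nested inside another is suppressed in favour of the outer one. Compound
  (adjacent different-motif) runs stay separate records. `N` terminates any
  run.

Perfection is a *length class*: runs of at least `perfect_min_len` (default
20 nt) are perfect, 18–19 nt runs are imperfect. With these defaults the only
imperfect runs are 3-copy hexanucleotides, 9-copy dinucleotides and 18-copy
mononucleotides, which is why hexanucleotide-heavy surveys report a large
imperfect fraction.

The miner itself scans each period `p` once, comparing the sequence with its
`p`-shifted self and reading maximal equality stretches from a run-length
encoding; a stretch of `L` matches is a run of `L + p` nt. This is linear in
sequence length per period. Its correctness is not taken on faith: the test
suite compares it record-by-record against a brute-force oracle that extends
every primitive motif at every start position, over a thousand randomized
sequences.

## Summary tables and rounding

`summarize_ssrs()` reproduces the standard survey layout: per-type counts
with shares of the grand total (2 decimals), per-motif counts with shares of
their type (1 decimal), repeat-number bins, per-cDNA multiplicity, and
perfect/imperfect tallies. Two conventions matter:

* **Rounding is half-up at fixed decimals** (`round_half_up()`), not R's
  default half-to-even, so reproduced table cells are bit-stable.
* **Repeat-number bins** are the integer partition `[3,9]`, `[10,15]`,
  `[16,20]`, `[21,∞)`. Published tables of this kind often label bins
  "3-9 / 10-15 / 15-20 / >20", which overlap at 15 and 20; a partition is
  used so each record lands in exactly one bin.
* **The incidence denominator is an explicit argument** (`n_screened`),
  never inferred from the records: survey reports commonly quote slightly
  different corpus sizes in different sections, so the caller must own the
  denominator. Two incidences are reported: SSR regions per 100 screened
  sequences (the figure such surveys headline) and the percent of screened
  sequences harboring at least one SSR.

## ORF context

Published pipelines delegate gene finding to external predictors; `cdnassr`
instead uses a deterministic six-frame longest-ORF scan (`find_longest_orf`):
the longest ATG-to-stop span across both strands and all three frames, with a
minimum length of `min_aa` codons (default 30, a conventional short-ORF
filter), ties broken plus-strand-first then leftmost. This is a deliberate
semantic simplification — it has no splice or codon-usage model — but it is
dependency-free, exactly reproducible, and sufficient for classifying repeat
position on cDNAs, which have no introns. Each SSR is labelled `FIVE_UTR`,
`CDS`, `THREE_UTR` (by its start position on the ORF's strand, ties to the
upstream region, with a `boundary` flag when the tract straddles a junction)
or `NONCODING` when no qualifying ORF exists. For trinucleotide repeats
inside the CDS, `in_frame` records whether the tract starts on a codon
boundary — the biologically interesting case, since in-frame copy-number
change preserves the reading frame.

## Anchoring, primers and in-silico PCR

* **Anchoring** (`anchor_cdna`) finds genomic placements by exact k-mer
  seeding (default `k = 21`) and ungapped full-length extension, accepting
  placements with at least 95% identity; both strands are searched and exact
  embeddings are always found with `matched_fraction = 1`. There is no
  gapped or spliced alignment — adequate for genomes in which the cDNA is
  present near-verbatim, and exactly right for the synthetic genomes.
* **Primer design** (`suggest_primers`) is a deterministic stand-in for
  interactive design tools: windows are scanned from the SSR-proximal flank
  end outwards, shortest length first (18–24 nt), and the first window
  satisfying the GC range (40–60%) and homopolymer cap (runs of at most 3)
  wins on each side. Deterministic choice makes the marker panel
  reproducible; the constraints are conventional, not thermodynamic — no Tm
  or dimer model is attempted.
* **In-silico PCR** (`match_probe_pair`) reports every interval where one
  primer matches the plus strand and the reverse complement of the other
  matches downstream within `max_product` (default 2000 nt), 3' ends facing
  inward, in both orientations, with exact matching by default
  (`max_mismatch = 0`). All valid pairings are reported; uniqueness is
  decided downstream, where `write_physical_map()` suffixes and warns about
  markers with multiple placements. Site finding uses Biostrings pattern
  matching; the pairing logic is tested against a brute-force oracle over
  hundreds of randomized genomes with planted sites.

Coordinates are 0-based half-open throughout (BED convention); the physical
map is emitted as BED with an Mbp display column (start/1e6, half-up to 3
decimals).

## Marker scoring and two-sided clustering

Allele calls are small integers per marker (band identities — agarose gels
score band presence, not sequence), with `NA` for failed lanes. A marker is
polymorphic when at least two distinct non-missing calls appear among the
scored accessions; the rate's denominator is always explicit because panels
are quoted against different baselines (pairs designed vs pairs that
amplified).

For clustering, the package makes three choices the underlying reports leave
open, all configurable:

* **Encoding.** Accession distances use a one-hot encoding of the calls
  (one indicator column per observed marker:allele pair), so the result does
  not depend on how alleles happen to be numbered. The display matrix and
  the marker dendrogram use the row-standardized numeric call matrix — the
  one-hot columns are marker:allele combinations and cannot index a marker
  tree.
* **Standardization.** `zscore_rows()` centres and scales each accession row
  to mean 0, sample SD 1 (the quantity heatmap colour scales show); rows
  with no spread are set to 0 and flagged rather than producing NaN.
* **Distance and linkage.** Euclidean distance, complete linkage — typical
  heatmap-package defaults. Markers missing in more than half the
  accessions are dropped with a warning; remaining missing values fall back
  on R's pairwise distance scaling. Cutting the accession tree at `k = 2`
  yields the group assignment, and `group_concordance()` quantifies
  agreement with external labels as the adjusted Rand index (closed-form
  pair-counting, cross-checked against an independent implementation in the
  tests).

## Enrichment

`hypergeom_enrichment()` is a plain over-representation test: for a term
annotating `K` of `N` universe genes with `n` genes selected and `k`
overlapping, the raw p-value is the upper tail `P[X >= k]` of the
hypergeometric distribution, adjusted across terms by Benjamini–Hochberg and
thresholded at adjusted p < 0.05. This deliberately replaces web-service
enrichment engines, whose proprietary multiple-testing corrections and
database versions are not reproducible offline; the 0.05 adjusted cutoff is
the one convention retained. The universe defaults to all annotated genes
and can be overridden — results are sensitive to that choice, and selected
genes outside the universe are an error rather than silently dropped.

## The synthetic-data module

Every stage is exercised against generated data with known truth:

* `gen_cdna_corpus()` plants repeat runs into i.i.d. uniform background with
  homopolymers capped (default 8 nt, safely below the 18 nt threshold). Each
  run gets one guard base per side chosen to break its periodicity, so truth
  coordinates are unambiguous; any assembly whose background or junctions
  accidentally create an 18 nt run, or blur a planted one, is redrawn. The
  default planting mix is trinucleotide-heavy with substantial hexa- and
  dinucleotide fractions (weights 7:405:658:128:98:545 across mono- to
  hexanucleotides) and repeat numbers of 3–28 copies depending on motif
  length, the composition seen in dicot cDNA surveys, so both perfection
  classes and all repeat-number bins are populated. Per-sequence SSR counts
  are Poisson with mean `ssr_density` (default 1).
* `gen_genome()` embeds each cDNA exactly once on a random chromosome and
  strand between random spacers; `gen_genotypes()` builds a two-group
  accession panel (default 9 cultivated + 2 wild, the classic small
  validation panel) in which a `divergence` fraction of markers carries a
  wild-private allele and about half of those also segregate within the
  cultivated group, giving 2–3 alleles per polymorphic marker and realistic
  substructure; `gen_annotation()` plants exactly one term with a chosen
  overlap against a selected gene set, all other terms drawing uniformly
  from the universe.
* All generators are seed-deterministic (identical seeds give byte-identical
  output) and restore the caller's RNG state.

What the synthetic data does **not** emulate: real transcript structure
(UTR/CDS composition biases, splice isoforms), sequencing or base-calling
error, interrupted/approximate repeats, paralogy (each cDNA occurs once in
the genome), gel-scoring error in genotypes, and the dependency structure of
real GO annotations. Passing tests therefore demonstrate algorithmic
correctness on clean inputs — exact recovery of planted truth — not
robustness to the noise of a real EST collection; on real data the miner's
guarantees still hold (it is oracle-equivalent on arbitrary ACGTN input),
but anchoring, primer design and clustering inherit the usual caveats of
their simple models.

## Problem sizes, numerical choices, degenerate inputs

The shipped tests and the acceptance script run at desk scale, chosen so the
whole suite completes in a few minutes on one CPU: oracle equivalence on
1,000 randomized 300-nt sequences, planted-truth recovery over 100 corpora
of 8 sequences, 200 randomized in-silico PCR genomes, a 60-cDNA round-trip
genome, and 100-seed clustering/enrichment simulations. The statistical
guarantees (exact recovery, oracle identity, closed-form p-values) are
size-independent; larger corpora only lengthen runtime linearly.

Degenerate inputs are contracts, not crashes: an empty sequence yields an
empty record table; an empty record table yields zero-count tables with `NA`
percents; a single accession yields an identity grouping with no tree;
constant matrix rows standardize to zero with a flag; a zero-overlap term
gets p = 1; an unsatisfiable primer window yields a zero-row tibble. Errors
are reserved for contract violations: non-IUPAC characters, repeat counts
below 3, an incidence denominator smaller than the observed cDNA count,
selected genes outside the universe, and pipeline stages whose inputs are
missing (the orchestrator aborts naming the stage).

## Known limitations

* The perfect/imperfect dichotomy is purely length-based; mismatch-tolerant
  ("interrupted") repeat detection is out of scope.
* The ORF scan is not a gene predictor; on genomic (intron-containing)
  input its region labels would be meaningless.
* Primer suggestions are constraint-based, not thermodynamic, and will not
  coincide with panels designed by interactive tools.
* The anchorer performs no gapped alignment; cDNAs spanning introns in a
  real genome will anchor partially or not at all.
* Enrichment results depend entirely on the annotation supplied; the package
  ships no ontology.
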
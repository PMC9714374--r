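# cdnassr

Genic microsatellite (SSR) marker development from cDNA/EST collections, as a
tidyverse-styled R package. Everything takes and returns tibbles, so the
stages chain with the pipe from raw FASTA to a physical marker map.

## The problem

Simple sequence repeats inside transcribed sequences (cDNA-SSRs, also called
EST-SSRs or genic SSRs) make attractive molecular markers: their flanks are
conserved gene sequence, so primers transfer well across germplasm, and
length variation in the repeat tract is easy to score on agarose gels. A
typical survey mines a cDNA collection for repeats, summarizes their motif
composition, designs primer pairs on the repeat flanks, places the markers on
a genome by in-silico PCR, and validates a panel on a set of accessions —
scoring polymorphism and checking that clustering of the genotype calls
separates known groups (for example cultivated accessions from wild
relatives).

`cdnassr` implements that whole workflow plus a synthetic-data module that
plants repeats, genome placements, genotype structure and an enriched
annotation term with known truth, so every stage is testable end to end
without downloading anything.

## The core definitions

* A detected SSR is a **maximal tandem repeat run** with fundamental
  (smallest) period *k* between 1 and 6 nt and full-period length
  `k x repeat_count >= 18` nt. Runs are labelled by their smallest period
  only — an `(AT)9` tract is one dinucleotide record, never also a tetra- or
  hexanucleotide — so per-type counts partition the records. Trailing
  partial motif copies are excluded; repeat numbers are whole.
* A run is **perfect** when its total length is at least 20 nt and
  **imperfect** at 18–19 nt. This is a length class, not a mismatch class.
* A **primitive motif** is a k-mer that is not a power of a shorter motif;
  there are 4, 12, 60, 240, 1020 and 4020 of them for k = 1..6.
* **In-silico PCR** reports every genomic interval where one primer matches
  the plus strand and the reverse complement of the other matches downstream
  within a product bound, 3' ends facing inward, in both orientations.
* A marker is **polymorphic** when it shows >= 2 distinct non-missing allele
  calls across the scored accessions. Rates are quoted against an explicit
  denominator (pairs designed vs pairs amplified differ in published panels).
* Term enrichment is an upper-tail hypergeometric test with
  Benjamini–Hochberg adjustment, significant below adjusted p = 0.05.

## Worked example

```r
library(cdnassr)

# a synthetic cDNA corpus with planted repeats
cfg <- synth_config(n_sequences = 50, length_range = c(300L, 900L),
                    ssr_density = 1, seed = 42)
corpus <- gen_cdna_corpus(cfg)

ssrs <- find_ssrs(corpus$sequences)
ssrs
#> # A tibble: 39 x 9
#>   seq_id     motif motif_class motif_len repeat_count start   end length perfect
#>   <chr>      <chr> <chr>           <int>        <int> <int> <int>  <int> <lgl>
#> 1 cdna_00001 GCC   CCG                 3            6   284   302     18 FALSE
#> 2 cdna_00001 AG    AG                  2           23   318   364     46 TRUE
#> # ... 37 more rows

summ <- summarize_ssrs(ssrs, n_screened = 50)
summ$type_table       # counts and shares per motif length
summ$incidence        # SSR regions per 100 screened sequences
autoplot(summ)        # bar chart of the type table

# genotype scoring and two-sided clustering on a synthetic 9+2 accession panel
gt  <- gen_genotypes(n_markers = 35, n_group1 = 9, n_group2 = 2,
                     divergence = 22/35, seed = 5)
pol <- score_polymorphism(gt$genotypes, denominator = 35)
pol
#> 22 of 35 markers polymorphic; rate 62.9% (denominator 35)
bc <- bicluster(gt$genotypes, k = 2)
tidy(bc)              # accession -> group at the k = 2 cut
group_concordance(bc$groups, gt$genotypes$group)
#> [1] 1
autoplot(bc)          # Z-score heatmap in dendrogram order
```

The printed polymorphism line reads: of the 35 markers in the panel, 22 show
at least two alleles, i.e. 62.9% against the panel denominator. A
concordance (adjusted Rand index) of 1 means the k = 2 cut of the accession
dendrogram recovers the planted cultivated/wild split exactly.

One command runs everything — mining, tables, ORF context, anchoring, primer
design, in-silico PCR, marker scoring, clustering and enrichment — on a
fully synthetic data set and writes one TSV/BED per result plus a checksummed
manifest:

```r
demo <- run_demo("demo_run", seed = 1)
list.files("demo_run/results")
```

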
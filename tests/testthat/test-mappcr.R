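test_that("anchoring recovers synthetic genome placements on both strands", {
  cfg <- synth_config(n_sequences = 8, length_range = c(300L, 500L),
                      ssr_density = 0.5, seed = 61)
  cc <- gen_cdna_corpus(cfg)
  g <- gen_genome(cc$sequences, flank_len = 150L, n_chromosomes = 2L, seed = 62)
  for (i in seq_len(nrow(g$placements))) {
    truth <- g$placements[i, ]
    got <- anchor_cdna(g$genome, cc$sequences[[truth$cdna_id]],
                       cdna_id = truth$cdna_id)
    expect_equal(nrow(got), 1)
    expect_equal(got$chrom, truth$chrom)
    expect_equal(got$start, as.integer(truth$start))
    expect_equal(got$end, as.integer(truth$end))
    expect_equal(got$strand, truth$strand)
    expect_equal(got$matched_fraction, 1)
  }
})

test_that("anchoring returns an empty table for absent cDNAs and errors on empty genomes", {
  genome <- c(chr1 = paste(rep(c("A", "C", "G", "T"), 100), collapse = ""))
  absent <- strrep("TTAGGCATCGTTAACGGATCAGT", 3)
  expect_equal(nrow(anchor_cdna(genome, absent)), 0)
  expect_error(anchor_cdna(character(0), absent), "empty")
  expect_error(anchor_cdna(genome, "ACGT", k = 21), "shorter")
})

test_that("anchoring tolerates mismatches down to the identity floor", {
  set.seed(63)
  cdna <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  pad <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  mutated <- cdna
  # 6 mismatches over 300 nt = 98% identity, above the 95% default floor
  for (pos in c(30, 80, 130, 180, 230, 280)) {
    old <- substr(mutated, pos, pos)
    substr(mutated, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  genome <- c(chr1 = paste0(pad, mutated, pad))
  got <- anchor_cdna(genome, cdna)
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 100L)
  expect_lt(got$matched_fraction, 1)
  expect_gte(got$matched_fraction, 0.95)
})

test_that("flank extraction clips at sequence boundaries and flags truncation", {
  s <- paste(rep("ACGT", 250), collapse = "")
  ssr_mid <- tibble::tibble(start = 425L, end = 475L)
  fl <- extract_flanks(s, ssr_mid, flank_len = 150)
  expect_equal(fl$left_len, 150L)
  expect_equal(fl$right_len, 150L)
  expect_false(fl$left_truncated || fl$right_truncated)
  expect_equal(fl$left, substr(s, 276, 425))
  expect_equal(fl$right, substr(s, 476, 625))

  ssr_start <- tibble::tibble(start = 0L, end = 30L)
  fl0 <- extract_flanks(s, ssr_start, flank_len = 150)
  expect_equal(fl0$left, "")
  expect_true(fl0$left_truncated)
  expect_false(fl0$right_truncated)
})

test_that("primer selection respects constraints and is innermost-deterministic", {
  # all-A flank: GC and homopolymer constraints are unsatisfiable
  bad <- strrep("A", 80)
  expect_equal(nrow(suggest_primers(bad, bad)), 0)

  set.seed(64)
  left <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  # fully relaxed constraints: the innermost minimum-length windows win
  pp <- suggest_primers(left, right, gc_range = c(0, 100),
                        max_homopolymer = 1000L)
  expect_equal(pp$fwd_offset, 0L)
  expect_equal(pp$rev_offset, 0L)
  expect_equal(pp$fwd_len, 18L)
  expect_equal(pp$fwd, substr(left, 83, 100))
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  expect_equal(pp$rev, rc(substr(right, 1, 18)))

  # constrained primers actually satisfy the constraints
  pp2 <- suggest_primers(left, right)
  if (nrow(pp2) == 1) {
    for (p in c(pp2$fwd, pp2$rev)) {
      b <- strsplit(p, "")[[1]]
      gc <- 100 * sum(b %in% c("G", "C")) / length(b)
      expect_gte(gc, 40); expect_lte(gc, 60)
      expect_lte(max(rle(b)$lengths), 3)
    }
  }
})

test_that("in-silico PCR finds a constructed amplicon with the exact product length", {
  set.seed(65)
  fwd <- "ACGTTGCAGGTCAATCGG"
  rev <- "TGCCATGGTCAACGTTGA"
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  insert <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                  collapse = "")
  pad <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
  genome <- c(chr1 = paste0(pad, fwd, insert, rc(rev), pad))
  hits <- match_probe_pair(genome, fwd, rev)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$product_len, nchar(fwd) + 100L + nchar(rev))
  expect_equal(hits$start, 50L)
  expect_equal(hits$orientation, "fwd_plus")

  # genome with no reverse site: nothing amplifies
  genome2 <- c(chr1 = paste0(pad, fwd, insert, pad))
  expect_equal(nrow(match_probe_pair(genome2, fwd, rev)), 0)

  # swapped orientation is found too
  genome3 <- c(chr1 = paste0(pad, rev, insert, rc(fwd), pad))
  hits3 <- match_probe_pair(genome3, fwd, rev)
  expect_equal(nrow(hits3), 1)
  expect_equal(hits3$orientation, "rev_plus")
})

test_that("in-silico PCR agrees with the brute-force site-pairing oracle", {
  set.seed(66)
  for (i in 1:60) {
    fwd <- paste(sample(c("A", "C", "G", "T"), 18, replace = TRUE), collapse = "")
    rev <- paste(sample(c("A", "C", "G", "T"), 18, replace = TRUE), collapse = "")
    rc <- function(s) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    n_sites <- sample(0:3, 1)
    pieces <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                    collapse = "")
    for (j in seq_len(n_sites)) {
      kind <- sample(c("pair", "fwd_only", "rev_only"), 1)
      gap <- paste(sample(c("A", "C", "G", "T"), sample(20:150, 1),
                          replace = TRUE), collapse = "")
      block <- switch(kind,
        pair = paste0(fwd, gap, rc(rev)),
        fwd_only = fwd,
        rev_only = rc(rev)
      )
      pieces <- paste0(pieces, block,
                       paste(sample(c("A", "C", "G", "T"), 100,
                                    replace = TRUE), collapse = ""))
    }
    genome <- c(chr1 = pieces)
    got <- as.data.frame(match_probe_pair(genome, fwd, rev, max_product = 500))
    want <- oracle_pcr(pieces, "chr1", fwd, rev, max_product = 500)
    got <- got[order(got$start, got$end, got$orientation), ]
    want <- want[order(want$start, want$end, want$orientation), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$product_len, want$product_len)
    expect_equal(got$orientation, want$orientation)
  }
})

test_that("flanks -> primers -> PCR round trip recovers each planted SSR's amplicon", {
  cfg <- synth_config(n_sequences = 30, length_range = c(500L, 800L),
                      ssr_density = 1, seed = 67)
  cc <- gen_cdna_corpus(cfg)
  g <- gen_genome(cc$sequences, flank_len = 200L, n_chromosomes = 2L, seed = 68)
  recs <- find_ssrs(cc$sequences)
  tested <- 0
  for (i in seq_len(nrow(recs))) {
    rec <- recs[i, ]
    cdna <- cc$sequences[[rec$seq_id]]
    fl <- extract_flanks(cdna, rec, flank_len = 150)
    pp <- suggest_primers(fl$left, fl$right)
    if (nrow(pp) == 0) next
    hits <- match_probe_pair(g$genome, pp$fwd, pp$rev, max_product = 2000)
    expect_equal(nrow(hits), 1)
    # the amplicon must contain the planted SSR's genomic interval
    pl <- g$placements[g$placements$cdna_id == rec$seq_id, ]
    if (pl$strand == "+") {
      ssr_g <- c(pl$start + rec$start, pl$start + rec$end)
    } else {
      L <- pl$end - pl$start
      ssr_g <- c(pl$start + L - rec$end, pl$start + L - rec$start)
    }
    expect_lte(hits$start, ssr_g[1])
    expect_gte(hits$end, ssr_g[2])
    tested <- tested + 1
  }
  expect_gte(tested, 15)
})

test_that("physical map BED output is sorted and flags ambiguous markers", {
  hits <- tibble::tibble(
    marker = c("m1", "m2", "m2", "m3"),
    chrom = c("chr2", "chr1", "chr2", "chr1"),
    start = c(100L, 500L, 40L, 10L),
    end = c(350L, 700L, 90L, 60L)
  )
  expect_warning(bed <- write_physical_map(hits), "ambiguous.*m2")
  expect_equal(bed$name, c("m3", "m2_1", "m2_2", "m1"))
  expect_equal(bed$chrom, c("chr1", "chr1", "chr2", "chr2"))
  expect_true(all(diff(bed$start[bed$chrom == "chr1"]) > 0))

  single <- tibble::tibble(marker = "marker1", chrom = "chr1",
                           start = 100L, end = 350L)
  b1 <- write_physical_map(single)
  expect_equal(unname(unlist(b1)), c("chr1", "100", "350", "marker1"))
  mb <- map_positions_mbp(b1)
  expect_equal(mb$pos_mbp, 0)

  tmp <- tempfile(fileext = ".bed")
  write_physical_map(single, tmp)
  expect_equal(readLines(tmp), "chr1\t100\t350\tmarker1")
})
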
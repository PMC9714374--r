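#' Configuration for the synthetic cDNA corpus generator
#'
#' Bundles and validates the knobs of [gen_cdna_corpus()]. The defaults
#' emulate a genic SSR survey of an EST/cDNA collection: per-type motif
#' weights follow the relative abundances typically seen in dicot cDNA
#' screens (trinucleotide-heavy, with substantial hexa- and dinucleotide
#' fractions), and repeat numbers span 3 to 28 copies depending on motif
#' length, so planted runs cover both the imperfect (18-19 nt) and perfect
#' (>= 20 nt) classes.
#'
#' @param n_sequences Number of cDNA sequences to generate.
#' @param length_range Two integers, min and max sequence length in nt.
#' @param ssr_density Expected number of planted SSRs per sequence (Poisson).
#' @param motif_type_weights Six non-negative weights for sampling the motif
#'   length (mono- to hexanucleotide) of each planted run.
#' @param repeat_count_range List of six `c(min, max)` integer pairs giving
#'   the repeat-number range per motif length. Each minimum must plant a run
#'   of at least `min_plant_len` nt.
#' @param background_max_homopolymer Longest single-base run allowed in
#'   background sequence; must stay below 18 so background never emits an
#'   accidental mononucleotide SSR.
#' @param min_plant_len Minimum total length in nt of any planted run.
#' @param seed Integer seed; identical seeds give byte-identical corpora.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_sequences = 200,
                         length_range = c(300L, 1200L),
                         ssr_density = 1,
                         motif_type_weights = c(7, 405, 658, 128, 98, 545),
                         repeat_count_range = list(
                           c(18L, 28L), c(9L, 28L), c(6L, 15L),
                           c(5L, 10L), c(4L, 8L), c(3L, 18L)
                         ),
                         background_max_homopolymer = 8L,
                         min_plant_len = 18L,
                         seed = 1L) {
  stopifnot(
    n_sequences >= 1,
    length(length_range) == 2, length_range[1] >= 30,
    length_range[2] >= length_range[1],
    ssr_density >= 0,
    length(motif_type_weights) == 6, all(motif_type_weights >= 0),
    sum(motif_type_weights) > 0,
    length(repeat_count_range) == 6,
    background_max_homopolymer >= 1
  )
  if (background_max_homopolymer >= 18) {
    stop("`background_max_homopolymer` must be < 18 so background cannot host an SSR",
         call. = FALSE)
  }
  for (k in 1:6) {
    rr <- repeat_count_range[[k]]
    stopifnot(length(rr) == 2, rr[1] >= 3, rr[2] >= rr[1])
    if (rr[1] * k < min_plant_len) {
      stop(sprintf("repeat_count_range[[%d]] minimum plants runs shorter than %d nt",
                   k, min_plant_len), call. = FALSE)
    }
  }
  structure(
    list(
      n_sequences = as.integer(n_sequences),
      length_range = as.integer(length_range),
      ssr_density = ssr_density,
      motif_type_weights = motif_type_weights,
      repeat_count_range = lapply(repeat_count_range, as.integer),
      background_max_homopolymer = as.integer(background_max_homopolymer),
      min_plant_len = as.integer(min_plant_len),
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

BASES <- c("A", "C", "G", "T")

# sample() treats a length-1 numeric x as 1:x; this keeps fixed ranges fixed
sample1 <- function(x) if (length(x) == 1) x else sample(x, 1)

# Random background bases with homopolymer runs capped at `maxh`.
random_background <- function(len, maxh) {
  if (len <= 0) return(character(0))
  b <- sample(BASES, len, replace = TRUE)
  repeat {
    r <- rle(b)
    long <- which(r$lengths > maxh)
    if (length(long) == 0) break
    ends <- cumsum(r$lengths)
    for (i in long) {
      # resample every base past the cap within this run
      s <- ends[i] - r$lengths[i] + 1
      fix <- seq(s + maxh, ends[i])
      b[fix] <- vapply(b[fix], function(x) sample(setdiff(BASES, x), 1), character(1))
    }
  }
  b
}

#' Generate a synthetic cDNA corpus with planted SSRs
#'
#' Builds `n_sequences` random cDNA-like sequences and plants tandem repeat
#' runs with known motif, copy number and offset. Each planted run is flanked
#' by one guard base on either side chosen to break the motif's periodicity,
#' so the maximal-run coordinates of the truth table are unambiguous.
#' Background is i.i.d. uniform with homopolymers capped; any sequence whose
#' background accidentally contains a >= `min_plant_len` nt repeat run, or
#' whose planted runs collide, is redrawn, so mining the corpus returns
#' exactly the planted set.
#'
#' @param config A [synth_config()] object.
#' @return A list with `sequences` (named character vector) and `truth`
#'   (tibble: `seq_id`, `motif`, `motif_len`, `repeat_count`, `start`
#'   0-based, `length`).
#' @export
gen_cdna_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    seqs <- character(config$n_sequences)
    names(seqs) <- sprintf("cdna_%05d", seq_len(config$n_sequences))
    truth <- vector("list", config$n_sequences)
    for (i in seq_len(config$n_sequences)) {
      res <- gen_one_cdna(config, names(seqs)[i])
      seqs[i] <- res$seq
      truth[[i]] <- res$truth
    }
    list(sequences = seqs, truth = dplyr::bind_rows(truth))
  })
}

gen_one_cdna <- function(config, seq_id) {
  len <- sample1(config$length_range[1]:config$length_range[2])
  n_ssr <- stats::rpois(1, config$ssr_density)
  fitted <- FALSE
  for (attempt in 1:200) {
    plant <- plan_plants(config, n_ssr)
    # blocks are guard + run + guard; they need room plus background between
    need <- sum(plant$block_len) + 2L * length(plant$block_len) +
      length(plant$block_len) + 1L
    if (need > len) next
    fitted <- TRUE
    res <- assemble_cdna(config, len, plant, seq_id)
    if (!is.null(res)) return(res)
  }
  if (!fitted) {
    stop("sequence too short to host the requested SSRs", call. = FALSE)
  }
  stop("could not assemble a clean synthetic sequence after 200 attempts",
       call. = FALSE)
}

plan_plants <- function(config, n_ssr) {
  if (n_ssr == 0) {
    return(list(motif = character(0), repeat_count = integer(0),
                block_len = integer(0)))
  }
  k <- sample(1:6, n_ssr, replace = TRUE, prob = config$motif_type_weights)
  motif <- vapply(k, function(kk) sample(enumerate_primitive_motifs(kk), 1), character(1))
  rc <- vapply(k, function(kk) {
    rr <- config$repeat_count_range[[kk]]
    as.integer(sample1(rr[1]:rr[2]))
  }, integer(1))
  list(motif = motif, repeat_count = rc, block_len = nchar(motif) * rc)
}

assemble_cdna <- function(config, len, plant, seq_id) {
  n_ssr <- length(plant$motif)
  maxh <- config$background_max_homopolymer
  if (n_ssr == 0) {
    s <- paste(random_background(len, maxh), collapse = "")
    if (nrow(accidental_runs(s, config$min_plant_len)) > 0) return(NULL)
    return(list(seq = s, truth = NULL))
  }
  blocks <- lapply(seq_len(n_ssr), function(j) {
    motif <- plant$motif[j]
    mb <- strsplit(motif, "", fixed = TRUE)[[1]]
    run <- strrep(motif, plant$repeat_count[j])
    left_guard <- sample(setdiff(BASES, mb[length(mb)]), 1)
    right_guard <- sample(setdiff(BASES, mb[1]), 1)
    c(left_guard, strsplit(run, "", fixed = TRUE)[[1]], right_guard)
  })
  block_tot <- sum(vapply(blocks, length, integer(1)))
  n_gaps <- n_ssr + 1L
  bg_tot <- len - block_tot
  if (bg_tot < n_gaps) return(NULL)
  # split background into gaps, each >= 1 nt so blocks never abut
  cuts <- sort(sample(seq_len(bg_tot - 1L), n_gaps - 1L))
  gap_len <- diff(c(0L, cuts, bg_tot))
  pieces <- character(0)
  starts <- integer(n_ssr)
  pos <- 0L
  for (j in seq_len(n_ssr)) {
    gap <- random_background(gap_len[j], maxh)
    pieces <- c(pieces, gap, blocks[[j]])
    pos <- pos + gap_len[j]
    starts[j] <- pos + 1L # skip the left guard; 0-based offset of the run
    pos <- pos + length(blocks[[j]])
  }
  pieces <- c(pieces, random_background(gap_len[n_gaps], maxh))
  s <- paste(pieces, collapse = "")
  truth <- tibble::tibble(
    seq_id = seq_id,
    motif = plant$motif,
    motif_len = nchar(plant$motif),
    repeat_count = plant$repeat_count,
    start = starts,
    length = nchar(plant$motif) * plant$repeat_count
  )
  truth <- truth[order(truth$start), ]
  # reject assemblies where background or junctions created extra runs, or
  # where an accidental extension blurred a planted run
  runs <- accidental_runs(s, config$min_plant_len)
  if (!identical(runs$start, truth$start) ||
      !identical(runs$length, truth$length) ||
      !identical(runs$motif_len, truth$motif_len)) {
    return(NULL)
  }
  list(seq = s, truth = truth)
}

# All maximal full-period runs >= min_len with a primitive start motif,
# described by (start0, full-period length, fundamental period). Used only to
# vet generated sequences against their planting plan.
accidental_runs <- function(s, min_len) {
  code <- match(strsplit(s, "", fixed = TRUE)[[1]], BASES)
  out <- list()
  for (p in 1:6) {
    runs <- scan_period_runs(code, p)
    if (nrow(runs) == 0) next
    rc <- runs$run_len %/% p
    full <- rc * p
    keep <- full >= min_len
    if (!any(keep)) next
    motif <- substring(s, runs$start[keep], runs$start[keep] + p - 1L)
    prim <- vapply(motif, is_primitive_motif, logical(1), USE.NAMES = FALSE)
    if (!any(prim)) next
    out[[p]] <- data.frame(start = as.integer(runs$start[keep][prim] - 1L),
                           length = as.integer(full[keep][prim]),
                           motif_len = as.integer(p))
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(start = integer(), length = integer(), motif_len = integer()))
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Embed a cDNA corpus in a synthetic genome
#'
#' Places each cDNA exactly once on a randomly chosen chromosome and strand,
#' separated by random background spacers, and records the placement truth.
#'
#' @param corpus Named character vector of cDNA sequences (e.g. the
#'   `sequences` element of [gen_cdna_corpus()]).
#' @param flank_len Guaranteed background spacer in nt on each side of every
#'   embedded cDNA (actual spacers vary between `flank_len` and
#'   `2 * flank_len`); `0` makes cDNAs abut.
#' @param n_chromosomes Number of chromosomes.
#' @param seed Integer seed.
#' @return A list with `genome` (named character vector `chr1..chrN`) and
#'   `placements` (tibble: `cdna_id`, `chrom`, `start` 0-based half-open,
#'   `end`, `strand`).
#' @export
gen_genome <- function(corpus, flank_len = 500L, n_chromosomes = 3L, seed = 1L) {
  stopifnot(length(corpus) >= 1, n_chromosomes >= 1, flank_len >= 0)
  corpus <- as_seq_set(corpus, "corpus")
  with_seed(seed, {
    chrom_of <- sort(sample(seq_len(n_chromosomes), length(corpus), replace = TRUE))
    strand <- sample(c("+", "-"), length(corpus), replace = TRUE)
    spacer_len <- function() {
      if (flank_len == 0) 0L else sample1(flank_len:(2L * flank_len))
    }
    genome <- character(n_chromosomes)
    names(genome) <- paste0("chr", seq_len(n_chromosomes))
    rows <- vector("list", length(corpus))
    idx <- 0L
    for (ch in seq_len(n_chromosomes)) {
      members <- which(chrom_of == ch)
      pieces <- character(0)
      pos <- 0L
      for (m in members) {
        idx <- idx + 1L
        sp <- spacer_len()
        spacer <- paste(random_background(sp, 8L), collapse = "")
        embedded <- if (strand[m] == "+") corpus[m] else revcomp_chr(corpus[m])
        pieces <- c(pieces, spacer, embedded)
        rows[[idx]] <- tibble::tibble(
          cdna_id = names(corpus)[m],
          chrom = names(genome)[ch],
          start = pos + sp,
          end = pos + sp + nchar(corpus[m]),
          strand = strand[m]
        )
        pos <- pos + sp + nchar(corpus[m])
      }
      tail_sp <- spacer_len()
      pieces <- c(pieces, paste(random_background(max(tail_sp, 50L), 8L), collapse = ""))
      genome[ch] <- paste(pieces, collapse = "")
    }
    list(genome = genome, placements = dplyr::bind_rows(rows))
  })
}

#' Generate a synthetic accession-by-marker genotype table
#'
#' Emulates an agarose-gel genotyping experiment on two accession groups
#' (e.g. cultivated accessions vs wild relatives). A `divergence` fraction of
#' markers is polymorphic with a group-diagnostic allele private to group 2;
#' a subset of those also segregates within group 1, so the cultivated group
#' can show substructure. Remaining markers are monomorphic. Allele calls are
#' small integers (band identities, not sizes); missing calls are `NA`.
#'
#' @param n_markers Number of markers (>= 1).
#' @param n_group1,n_group2 Accessions in group 1 ("cultivated") and group 2
#'   ("wild").
#' @param divergence Fraction of markers carrying a group-diagnostic allele.
#' @param within_group1 Probability that a diagnostic marker also segregates
#'   within group 1 (giving it 3 alleles instead of 2).
#' @param missing_rate Per-call probability of a missing (`NA`) genotype.
#' @param seed Integer seed.
#' @return A list with `genotypes` (tibble: `accession`, `group`, one column
#'   per marker) and `truth` (tibble: `marker`, `polymorphic`, `diagnostic`,
#'   `cultivated_polymorphic`).
#' @export
gen_genotypes <- function(n_markers, n_group1 = 9L, n_group2 = 2L,
                          divergence = 0.5, within_group1 = 0.5,
                          missing_rate = 0, seed = 1L) {
  if (n_markers < 1) stop("`n_markers` must be >= 1", call. = FALSE)
  stopifnot(divergence >= 0, divergence <= 1, n_group1 >= 1, n_group2 >= 1)
  with_seed(seed, {
    n_acc <- n_group1 + n_group2
    acc <- c(sprintf("cult_%02d", seq_len(n_group1)),
             sprintf("wild_%02d", seq_len(n_group2)))
    group <- rep(c("cultivated", "wild"), c(n_group1, n_group2))
    n_diag <- round(n_markers * divergence)
    diag_idx <- if (n_diag > 0) sort(sample(seq_len(n_markers), n_diag)) else integer(0)
    calls <- matrix(1L, nrow = n_acc, ncol = n_markers,
                    dimnames = list(acc, sprintf("M%03d", seq_len(n_markers))))
    cult_poly <- logical(n_markers)
    for (j in diag_idx) {
      if (stats::runif(1) < within_group1 && n_group1 >= 2) {
        split <- sample(c(1L, 2L), n_group1, replace = TRUE)
        # guarantee both alleles appear within group 1
        if (length(unique(split)) == 1) split[sample(n_group1, 1)] <- 3L - split[1]
        calls[seq_len(n_group1), j] <- split
        calls[n_group1 + seq_len(n_group2), j] <- 3L
        cult_poly[j] <- TRUE
      } else {
        calls[seq_len(n_group1), j] <- 1L
        calls[n_group1 + seq_len(n_group2), j] <- 2L
      }
    }
    if (missing_rate > 0) {
      drop <- stats::runif(length(calls)) < missing_rate
      calls[drop] <- NA_integer_
    }
    genotypes <- tibble::tibble(accession = acc, group = group,
                                tibble::as_tibble(calls))
    truth <- tibble::tibble(
      marker = colnames(calls),
      polymorphic = seq_len(n_markers) %in% diag_idx,
      diagnostic = seq_len(n_markers) %in% diag_idx,
      cultivated_polymorphic = cult_poly
    )
    list(genotypes = genotypes, truth = truth)
  })
}

#' Generate a synthetic gene-to-term annotation with one planted term
#'
#' Builds a gene universe, a selected gene set, and `n_terms` annotation
#' terms. Exactly one term (the planted one) overlaps the selected set by
#' `selected_overlap` genes; all other terms draw their genes uniformly from
#' the universe, so their overlaps sit at random expectation.
#'
#' @param n_genes Universe size.
#' @param n_terms Number of terms.
#' @param enriched_term_size Size of the planted term.
#' @param selected_size Size of the selected gene set.
#' @param selected_overlap Overlap between the planted term and the selected
#'   set; must not exceed `min(enriched_term_size, selected_size)`.
#' @param term_size_range Size range for the non-planted terms.
#' @param seed Integer seed.
#' @return A list with `annotation` (tibble: `gene_id`, `term_id`),
#'   `universe` (all gene ids), `selected` (character vector) and
#'   `planted_term` (its id).
#' @export
gen_annotation <- function(n_genes, n_terms, enriched_term_size,
                           selected_size, selected_overlap,
                           term_size_range = c(10L, 50L), seed = 1L) {
  stopifnot(n_genes >= 1, n_terms >= 1, enriched_term_size >= 1,
            selected_size >= 1)
  if (enriched_term_size > n_genes) {
    stop("`enriched_term_size` cannot exceed `n_genes`", call. = FALSE)
  }
  if (selected_overlap > min(enriched_term_size, selected_size)) {
    stop("`selected_overlap` cannot exceed the smaller of term size and selected size",
         call. = FALSE)
  }
  with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    selected <- sort(sample(genes, selected_size))
    planted <- c(
      sample(selected, selected_overlap),
      sample(setdiff(genes, selected), enriched_term_size - selected_overlap)
    )
    term_ids <- sprintf("T%03d", seq_len(n_terms))
    members <- vector("list", n_terms)
    members[[1]] <- sort(planted)
    if (n_terms > 1) {
      for (t in 2:n_terms) {
        sz <- sample1(max(1L, term_size_range[1]):min(n_genes, term_size_range[2]))
        members[[t]] <- sort(sample(genes, sz))
      }
    }
    annotation <- tibble::tibble(
      gene_id = unlist(members),
      term_id = rep(term_ids, lengths(members))
    )
    list(annotation = annotation, universe = genes, selected = selected,
         planted_term = term_ids[1])
  })
}
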
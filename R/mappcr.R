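#' Anchor a cDNA on a genome by seeded ungapped alignment
#'
#' Finds genomic placements of a cDNA by exact k-mer seeding followed by
#' ungapped full-length extension, accepting placements with at least
#' `min_identity` matching bases. Both strands are searched; exact substring
#' embeddings are always found with `matched_fraction = 1`.
#'
#' @param genome FASTA path, DNAStringSet or named character vector of
#'   chromosome sequences.
#' @param cdna A single cDNA sequence (character), at least `k` nt long.
#' @param cdna_id Identifier recorded in the output.
#' @param k Seed length in nt.
#' @param min_identity Minimum fraction of matching bases over the full cDNA
#'   length.
#' @return Tibble with `cdna_id`, `chrom`, `start`, `end` (0-based half-open,
#'   plus-strand genomic), `strand` and `matched_fraction`, sorted by
#'   chromosome and start.
#' @export
anchor_cdna <- function(genome, cdna, cdna_id = "cdna", k = 21,
                        min_identity = 0.95) {
  genome <- as_seq_set(genome, "genome")
  if (length(genome) == 0 || all(nchar(genome) == 0)) {
    stop("`genome` is empty", call. = FALSE)
  }
  cdna <- toupper(cdna)
  L <- nchar(cdna)
  if (L < k) stop("cDNA shorter than the seed length `k`", call. = FALSE)
  gset <- Biostrings::DNAStringSet(genome)
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") cdna else revcomp_chr(cdna)
    seed_off <- unique(c(seq(1L, L - k + 1L, by = k), L - k + 1L))
    for (ci in seq_along(gset)) {
      chrom_seq <- genome[[ci]]
      clen <- nchar(chrom_seq)
      starts <- integer(0)
      for (off in seed_off) {
        seed <- substr(q, off, off + k - 1L)
        m <- Biostrings::matchPattern(seed, gset[[ci]])
        if (length(m) == 0) next
        starts <- c(starts, Biostrings::start(m) - (off - 1L))
      }
      starts <- sort(unique(starts))
      starts <- starts[starts >= 1 & starts + L - 1 <= clen]
      for (st in starts) {
        window <- substr(chrom_seq, st, st + L - 1L)
        ident <- sum(strsplit(window, "", fixed = TRUE)[[1]] ==
                       strsplit(q, "", fixed = TRUE)[[1]]) / L
        if (ident >= min_identity) {
          hits[[length(hits) + 1]] <- tibble::tibble(
            cdna_id = cdna_id, chrom = names(genome)[ci],
            start = st - 1L, end = st - 1L + L,
            strand = strand, matched_fraction = ident
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble::tibble(cdna_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), matched_fraction = double()))
  }
  dplyr::arrange(dplyr::distinct(out), .data$chrom, .data$start, .data$strand)
}

#' Extract SSR flanking sequences
#'
#' @param sequence The host DNA sequence (single character string).
#' @param ssr A one-row SSR record (tibble with 0-based half-open `start`,
#'   `end`).
#' @param flank_len Flank length in nt on each side.
#' @return One-row tibble with `left`, `right`, `left_len`, `right_len` and
#'   truncation flags set when a flank is shorter than `flank_len` because it
#'   hit a sequence boundary.
#' @export
extract_flanks <- function(sequence, ssr, flank_len = 150) {
  stopifnot(nrow(ssr) == 1)
  L <- nchar(sequence)
  if (ssr$start < 0 || ssr$end > L) {
    stop("SSR coordinates fall outside the sequence", call. = FALSE)
  }
  left_from <- max(0L, ssr$start - flank_len)
  right_to <- min(L, ssr$end + flank_len)
  left <- substr(sequence, left_from + 1L, ssr$start)
  right <- substr(sequence, ssr$end + 1L, right_to)
  tibble::tibble(
    left = left, right = right,
    left_len = nchar(left), right_len = nchar(right),
    left_truncated = nchar(left) < flank_len,
    right_truncated = nchar(right) < flank_len
  )
}

primer_window_ok <- function(w, gc_range, max_homopolymer) {
  !grepl("[^ACGT]", w) &&
    gc_percent(w) >= gc_range[1] && gc_percent(w) <= gc_range[2] &&
    max_homopolymer_run(w) <= max_homopolymer
}

#' Suggest a primer pair from SSR flanks
#'
#' Chooses the forward primer from the left flank and the reverse primer as
#' the reverse complement of a right-flank window. The choice is
#' deterministic: windows are scanned from the SSR-proximal end outwards, and
#' for each offset primer lengths are tried shortest first; the first window
#' satisfying the GC and homopolymer constraints wins.
#'
#' @param left,right Flank sequences (SSR-adjacent ends face the repeat).
#' @param primer_len Two integers, min and max primer length in nt.
#' @param gc_range Two numbers, allowed GC percentage range (inclusive).
#' @param max_homopolymer Longest allowed single-base run within a primer.
#' @return One-row tibble with `fwd`, `rev` (both written 5'->3'),
#'   `fwd_offset`/`rev_offset` (distance in nt from the SSR) and
#'   `fwd_len`/`rev_len`, or a zero-row tibble when either flank has no
#'   satisfying window.
#' @export
suggest_primers <- function(left, right, primer_len = c(18L, 24L),
                            gc_range = c(40, 60), max_homopolymer = 3L) {
  if (nchar(left) < primer_len[1] || nchar(right) < primer_len[1]) {
    return(empty_primer_pair())
  }
  pick <- function(flank, side) {
    n <- nchar(flank)
    for (off in 0:(n - primer_len[1])) {
      for (len in primer_len[1]:primer_len[2]) {
        if (off + len > n) break
        w <- if (side == "left") {
          substr(flank, n - off - len + 1L, n - off)
        } else {
          substr(flank, off + 1L, off + len)
        }
        if (primer_window_ok(w, gc_range, max_homopolymer)) {
          return(list(window = w, offset = off, len = len))
        }
      }
    }
    NULL
  }
  f <- pick(left, "left")
  r <- pick(right, "right")
  if (is.null(f) || is.null(r)) return(empty_primer_pair())
  tibble::tibble(
    fwd = f$window, rev = revcomp_chr(r$window),
    fwd_offset = f$offset, rev_offset = r$offset,
    fwd_len = f$len, rev_len = r$len
  )
}

empty_primer_pair <- function() {
  tibble::tibble(fwd = character(), rev = character(),
                 fwd_offset = integer(), rev_offset = integer(),
                 fwd_len = integer(), rev_len = integer())
}

#' Predict PCR amplicons for a primer pair (in-silico PCR)
#'
#' Reports every genomic interval where one primer matches the plus strand
#' and the reverse complement of the other matches downstream within
#' `max_product`, with 3' ends facing inward. Both orientations are searched
#' (`fwd_plus`: forward primer on the plus strand; `rev_plus`: the swapped
#' arrangement), and all valid pairings are reported.
#'
#' @param genome FASTA path, DNAStringSet or named character vector.
#' @param fwd,rev Primer sequences, 5'->3', over `{A,C,G,T}`.
#' @param max_product Maximum amplicon length in nt.
#' @param max_mismatch Mismatches tolerated per primer site (exact by
#'   default).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `product_len` and `orientation`, sorted by chromosome and start.
#' @export
match_probe_pair <- function(genome, fwd, rev, max_product = 2000,
                             max_mismatch = 0) {
  genome <- as_seq_set(genome, "genome")
  fwd <- toupper(fwd); rev <- toupper(rev)
  check_dna(c(fwd, rev), allow_n = FALSE)
  gset <- Biostrings::DNAStringSet(genome)
  site_starts <- function(p, subject) {
    m <- Biostrings::matchPattern(p, subject, max.mismatch = max_mismatch)
    Biostrings::start(m)
  }
  hits <- list()
  for (ci in seq_along(gset)) {
    subject <- gset[[ci]]
    combos <- list(
      list(left = fwd, right = revcomp_chr(rev), orientation = "fwd_plus"),
      list(left = rev, right = revcomp_chr(fwd), orientation = "rev_plus")
    )
    for (cb in combos) {
      ls <- site_starts(cb$left, subject)
      rs <- site_starts(cb$right, subject)
      if (length(ls) == 0 || length(rs) == 0) next
      len_l <- nchar(cb$left); len_r <- nchar(cb$right)
      for (i in ls) {
        ends <- rs[rs >= i] + len_r - 1L
        prods <- ends - i + 1L
        ok <- prods <= max_product & prods >= max(len_l, len_r)
        for (e in ends[ok]) {
          hits[[length(hits) + 1]] <- tibble::tibble(
            chrom = names(genome)[ci],
            start = i - 1L, end = as.integer(e),
            product_len = as.integer(e - i + 1L),
            orientation = cb$orientation
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), product_len = integer(),
                          orientation = character()))
  }
  dplyr::arrange(dplyr::distinct(out), .data$chrom, .data$start, .data$end)
}

#' Write a physical marker map in BED format
#'
#' One BED line per marker placement, sorted by chromosome then start.
#' Markers with several genomic hits have their name suffixed `_1`, `_2`, ...
#' and are reported with a warning, since their map position is ambiguous.
#'
#' @param hits Tibble of amplicon hits with a `marker` column plus `chrom`,
#'   `start`, `end`.
#' @param path Optional output file; when given, tab-separated BED (no
#'   header) is written there.
#' @return Tibble of BED records (`chrom`, `start`, `end`, `name`),
#'   invisibly when `path` is given.
#' @export
write_physical_map <- function(hits, path = NULL) {
  stopifnot(all(c("marker", "chrom", "start", "end") %in% names(hits)))
  bed <- hits |>
    dplyr::group_by(.data$marker) |>
    dplyr::mutate(
      .n = dplyr::n(),
      name = if (dplyr::n() > 1) paste0(.data$marker, "_", dplyr::row_number())
             else .data$marker
    ) |>
    dplyr::ungroup()
  amb <- unique(bed$marker[bed$.n > 1])
  if (length(amb) > 0) {
    warning("ambiguous placement for marker(s): ", paste(amb, collapse = ", "),
            call. = FALSE)
  }
  bed <- bed |>
    dplyr::select("chrom", "start", "end", "name") |>
    dplyr::arrange(.data$chrom, .data$start)
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}

#' Positions in Mbp for display
#'
#' @param bed BED tibble from [write_physical_map()].
#' @return `bed` with a `pos_mbp` column (`start / 1e6`, half-up to 3
#'   decimals), the conventional unit for physical marker maps.
#' @export
map_positions_mbp <- function(bed) {
  bed$pos_mbp <- round_half_up(bed$start / 1e6, 3)
  bed
}
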
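STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find the longest open reading frame in a sequence
#'
#' Deterministic six-frame scan for the longest ATG-to-stop span. The ORF must
#' start with ATG and end with an in-frame stop codon inside the sequence.
#' Ties are broken in favour of the plus strand, then the smallest start.
#' Coordinates are 0-based half-open *on the reported strand* (for a minus
#' strand call, on the reverse complement) and include the stop codon.
#'
#' @param seq A single DNA string over `{A,C,G,T,N}`.
#' @param min_aa Minimum ORF length in coding codons (stop excluded).
#' @return A one-row tibble with `start`, `end`, `strand`, `frame`,
#'   `length_aa`, or a zero-row tibble when no qualifying ORF exists.
#' @export
#' @examples
#' find_longest_orf("ATGAAATAA", min_aa = 1)
find_longest_orf <- function(seq, min_aa = 30) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  check_dna(seq)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp_chr(seq)
    n <- nchar(s)
    for (frame in 0:2) {
      n_codons <- (n - frame) %/% 3
      if (n_codons < 2) next
      starts <- frame + 3 * (seq_len(n_codons) - 1) + 1
      codons <- substring(s, starts, starts + 2)
      is_start <- codons == "ATG"
      is_stop <- codons %in% STOP_CODONS
      # for every ATG, the next in-frame stop at or after it
      stop_pos <- which(is_stop)
      if (length(stop_pos) == 0 || !any(is_start)) next
      for (a in which(is_start)) {
        nxt <- stop_pos[stop_pos >= a]
        if (length(nxt) == 0) break
        b <- nxt[1]
        len_aa <- b - a # coding codons, stop excluded
        if (len_aa < min_aa) next
        cand <- list(start = starts[a] - 1L, end = starts[b] + 2L,
                     strand = strand, frame = frame, length_aa = len_aa)
        if (is.null(best) ||
            (cand$end - cand$start) > (best$end - best$start) ||
            ((cand$end - cand$start) == (best$end - best$start) &&
             better_tie(cand, best))) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), frame = integer(),
                          length_aa = integer()))
  }
  tibble::tibble(start = as.integer(best$start), end = as.integer(best$end),
                 strand = best$strand, frame = as.integer(best$frame),
                 length_aa = as.integer(best$length_aa))
}

better_tie <- function(cand, best) {
  if (cand$strand != best$strand) return(cand$strand == "+")
  cand$start < best$start
}

#' Locate SSRs relative to the longest ORF of their host sequence
#'
#' Classifies each SSR as `FIVE_UTR`, `CDS`, `THREE_UTR` or `NONCODING`
#' (no qualifying ORF) by the position of its start relative to the ORF on
#' the ORF's strand. An SSR straddling a region boundary is classified by its
#' start (ties go to the upstream region) and flagged in the `boundary`
#' column. For trinucleotide SSRs inside the CDS, `in_frame` records whether
#' the repeat tract starts on a codon boundary; elsewhere it is `NA`.
#'
#' @param x Sequences (FASTA path, DNAStringSet or named character vector).
#' @param records SSR record tibble from [find_ssrs()] for those sequences.
#' @param min_aa Passed to [find_longest_orf()].
#' @return `records` with `region`, `in_frame`, `boundary` and the ORF
#'   coordinates (`orf_start`, `orf_end`, `orf_strand`) appended.
#' @export
locate_ssr_in_gene <- function(x, records, min_aa = 30) {
  seqs <- as_seq_set(x)
  check_dna(seqs)
  orfs <- purrr::map(seqs, find_longest_orf, min_aa = min_aa)
  out <- records
  out$region <- "NONCODING"
  out$in_frame <- NA
  out$boundary <- FALSE
  out$orf_start <- NA_integer_
  out$orf_end <- NA_integer_
  out$orf_strand <- NA_character_
  for (i in seq_len(nrow(out))) {
    id <- out$seq_id[i]
    if (!id %in% names(orfs)) {
      stop(sprintf("SSR record references unknown sequence '%s'", id), call. = FALSE)
    }
    orf <- orfs[[id]]
    if (nrow(orf) == 0) next
    L <- nchar(seqs[[id]])
    # SSR interval on the ORF's strand (0-based half-open)
    if (orf$strand == "+") {
      s <- out$start[i]; e <- out$end[i]
    } else {
      s <- L - out$end[i]; e <- L - out$start[i]
    }
    region <- if (s < orf$start) "FIVE_UTR" else if (s < orf$end) "CDS" else "THREE_UTR"
    boundary <- (s < orf$start & e > orf$start) | (s < orf$end & e > orf$end)
    in_frame <- if (region == "CDS" && out$motif_len[i] == 3) {
      (s - orf$start) %% 3 == 0
    } else {
      NA
    }
    out$region[i] <- region
    out$in_frame[i] <- in_frame
    out$boundary[i] <- boundary
    out$orf_start[i] <- orf$start
    out$orf_end[i] <- orf$end
    out$orf_strand[i] <- orf$strand
  }
  out
}
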
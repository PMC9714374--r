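#' Enumerate primitive DNA motifs of a given length
#'
#' A motif is *primitive* when it is not a whole-number power of a shorter
#' motif, i.e. its fundamental (smallest) period equals its length. Only
#' primitive motifs can label a maximal repeat run: `ATAT` runs are really
#' `AT` runs. Counts obey the recurrence
#' `|P(k)| = 4^k - sum over proper divisors d of k of |P(d)|`,
#' giving 4, 12, 60, 240, 1020 and 4020 for k = 1..6.
#'
#' @param k Motif length, an integer between 1 and 6.
#' @return Character vector of all primitive k-mers, in lexicographic order.
#' @export
#' @examples
#' enumerate_primitive_motifs(1)
#' length(enumerate_primitive_motifs(2)) # 12
enumerate_primitive_motifs <- function(k) {
  if (length(k) != 1 || is.na(k) || k != as.integer(k) || k < 1 || k > 6) {
    stop("`k` must be a single integer between 1 and 6", call. = FALSE)
  }
  k <- as.integer(k)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid, c(rep(list(bases), k), stringsAsFactors = FALSE))
  # expand.grid varies the first column fastest; reverse for lexicographic order
  motifs <- do.call(paste0, rev(grid))
  motifs <- sort(motifs)
  motifs[vapply(motifs, is_primitive_motif, logical(1))]
}

# TRUE when `motif` is not a repetition of any shorter motif whose length
# divides the motif length.
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1) return(TRUE)
  for (d in seq_len(k - 1)) {
    if (k %% d != 0) next
    unit <- substr(motif, 1, d)
    if (strrep(unit, k %/% d) == motif) return(FALSE)
  }
  TRUE
}

# Lexicographically minimal rotation of a motif (same strand; reverse
# complements are never merged).
minimal_rotation <- function(motif) {
  k <- nchar(motif)
  if (k == 1) return(motif)
  doubled <- paste0(motif, motif)
  rots <- vapply(seq_len(k), function(i) substr(doubled, i, i + k - 1), character(1))
  min(rots)
}

#' Minimum repeat number reaching a length threshold
#'
#' @param motif_len Motif length in nt (1-6).
#' @param min_len Minimum total run length in nt.
#' @return `ceiling(min_len / motif_len)`, the smallest whole number of motif
#'   copies whose total length reaches `min_len`.
#' @export
#' @examples
#' min_repeats_for_threshold(6, 18) # 3
#' min_repeats_for_threshold(4, 18) # 5
min_repeats_for_threshold <- function(motif_len, min_len) {
  stopifnot(motif_len >= 1, motif_len <= 6, min_len >= 1)
  as.integer(ceiling(min_len / motif_len))
}

# Maximal period-p runs in an integer-coded sequence.
# Returns a data.frame with 1-based run start and the run length in nt of the
# *untrimmed* maximal run (partial trailing period included). `N` (coded NA)
# never participates. Shared by the miner and the synthetic-corpus guard.
scan_period_runs <- function(code, p) {
  n <- length(code)
  if (n < 2 * p) return(data.frame(start = integer(), run_len = integer()))
  a <- code[seq_len(n - p)]
  b <- code[seq_len(n - p) + p]
  ok <- !is.na(a) & !is.na(b) & a == b
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], run_len = r$lengths[keep] + p)
}

#' Detect microsatellite (SSR) runs in DNA sequences
#'
#' Finds every maximal tandem repeat run with fundamental period 1-6 nt whose
#' full-period length is at least `min_len` (default 18 nt). Each run is
#' labelled by its smallest period only, so an `(AT)9` run is reported once as
#' a dinucleotide, never again as a tetra- or hexanucleotide. A trailing
#' partial motif copy is excluded from the reported interval, so repeat
#' numbers are whole. Runs are *perfect* when their total length reaches
#' `perfect_min_len` (default 20 nt) and *imperfect* below it — a length
#' class, not a mismatch class. `N` terminates any run.
#'
#' @param x A FASTA path, a [Biostrings::DNAStringSet] or a (named) character
#'   vector of DNA sequences over `{A,C,G,T,N}`.
#' @param min_len Minimum full-period run length in nt to report.
#' @param perfect_min_len Total length at or above which a run is classified
#'   perfect.
#' @return A tibble with one row per run: `seq_id`, `motif` (as phased at the
#'   run start), `motif_class` (minimal rotation, strand preserved),
#'   `motif_len`, `repeat_count`, `start`/`end` (0-based half-open),
#'   `length` (nt, `= motif_len * repeat_count`) and `perfect`. Rows are
#'   sorted by sequence, then `start`, then `motif_len`; no row's interval is
#'   nested inside another row's.
#' @export
#' @examples
#' find_ssrs(c(x = paste0("G", strrep("AT", 9), "C")))
find_ssrs <- function(x, min_len = 18, perfect_min_len = 20) {
  seqs <- as_seq_set(x)
  check_dna(seqs)
  recs <- purrr::imap(seqs, function(s, id) find_ssrs_one(s, id, min_len))
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      seq_id = character(), motif = character(), motif_class = character(),
      motif_len = integer(), repeat_count = integer(),
      start = integer(), end = integer(), length = integer()
    )
  }
  classify_perfection(out, perfect_min_len)
}

find_ssrs_one <- function(seq, seq_id, min_len) {
  n <- nchar(seq)
  if (n == 0) return(NULL)
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  rows <- vector("list", 6)
  for (p in 1:6) {
    runs <- scan_period_runs(code, p)
    if (nrow(runs) == 0) next
    repeat_count <- runs$run_len %/% p
    full_len <- repeat_count * p
    keep <- full_len >= min_len
    if (!any(keep)) next
    runs <- runs[keep, , drop = FALSE]
    repeat_count <- repeat_count[keep]
    full_len <- full_len[keep]
    motif <- substring(seq, runs$start, runs$start + p - 1L)
    prim <- vapply(motif, is_primitive_motif, logical(1), USE.NAMES = FALSE)
    if (!any(prim)) next
    rows[[p]] <- tibble::tibble(
      seq_id = seq_id,
      motif = motif[prim],
      motif_len = rep.int(p, sum(prim)),
      repeat_count = as.integer(repeat_count[prim]),
      start = as.integer(runs$start[prim] - 1L),
      length = as.integer(full_len[prim])
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(NULL)
  out$end <- out$start + out$length
  out <- drop_nested_runs(out)
  out$motif_class <- vapply(out$motif, minimal_rotation, character(1), USE.NAMES = FALSE)
  out[order(out$start, out$motif_len),
      c("seq_id", "motif", "motif_class", "motif_len", "repeat_count",
        "start", "end", "length")]
}

# Remove runs whose interval is strictly contained in another run's interval
# (within one sequence); only the outer maximal run is reported.
drop_nested_runs <- function(df) {
  if (nrow(df) < 2) return(df)
  nested <- vapply(seq_len(nrow(df)), function(i) {
    any(df$start <= df$start[i] & df$end >= df$end[i] &
          (df$start < df$start[i] | df$end > df$end[i]))
  }, logical(1))
  df[!nested, , drop = FALSE]
}

#' Set the perfect/imperfect flag on SSR records
#'
#' Perfection here is a length class: a run is perfect when its total length
#' reaches `perfect_min_len` nt and imperfect otherwise. With the default
#' 18 nt detection threshold and 20 nt perfection threshold, the only
#' imperfect runs are 18-19 nt ones — e.g. a 3-copy hexanucleotide (18 nt) or
#' a 9-copy dinucleotide (18 nt).
#'
#' @param records A tibble of SSR records as returned by [find_ssrs()].
#' @param perfect_min_len Minimum total length in nt for a perfect run.
#' @return `records` with a logical `perfect` column (re)computed.
#' @export
classify_perfection <- function(records, perfect_min_len = 20) {
  records$perfect <- records$length >= perfect_min_len
  records
}
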
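#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file (gzip accepted).
#' @return Named character vector of upper-case sequences; names are the
#'   first whitespace-delimited token of each description line.
#' @export
read_fasta <- function(path) {
  as_seq_set(path)
}

#' Write SSR records to TSV
#'
#' Writes the record table with both the internal 0-based half-open
#' coordinates (`start`, `end`) and 1-based inclusive coordinates
#' (`start1`, `end1`) for human readers.
#'
#' @param records SSR record tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ssrs <- function(records, path) {
  out <- records
  out$start1 <- out$start + 1L
  out$end1 <- out$end
  write_tsv_plain(out, path)
}

# Deterministic TSV writer used for all pipeline outputs.
write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an SSR record TSV written by [write_ssrs()]
#'
#' @param path TSV file.
#' @return SSR record tibble (0-based half-open coordinates).
#' @export
read_ssrs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df[, c("seq_id", "motif", "motif_class", "motif_len",
                           "repeat_count", "start", "end", "length", "perfect")])
}
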
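# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never perturb the user's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Round half away from zero
#'
#' Fixed decimal rounding with ties going up (`0.5 -> 1`), the convention used
#' throughout the printed summary tables so that reproduced percentages are
#' bit-stable. Base [round()] rounds half to even, which would make printed
#' values depend on floating-point parity.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Reverse complement of plain character DNA (ACGTN), vectorised.
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Coerce FASTA path / DNAStringSet / named character vector to a named,
# upper-case character vector of sequences.
as_seq_set <- function(x, arg = "x") {
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (is.character(x) && length(x) == 1 && grepl("[^ACGTNacgtn]", x) && file.exists(x)) {
    out <- as.character(Biostrings::readDNAStringSet(x))
  } else if (is.character(x)) {
    out <- x
  } else {
    stop(sprintf("`%s` must be a FASTA path, a DNAStringSet or a character vector", arg),
         call. = FALSE)
  }
  out <- toupper(out)
  if (length(out) == 0) return(stats::setNames(character(0), character(0)))
  if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  # FASTA descriptions: keep the first whitespace-delimited token as the id
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

check_dna <- function(seq, allow_n = TRUE) {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, seq)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T", if (allow_n) ",N", "}",
         call. = FALSE)
  }
  invisible(TRUE)
}

# GC percentage of a plain character sequence.
gc_percent <- function(s) {
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

# Length of the longest single-base run.
max_homopolymer_run <- function(s) {
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(b) == 0) return(0L)
  max(rle(b)$lengths)
}
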
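# Independent brute-force oracles. These deliberately share no code with the
# package internals: primitivity is tested by substring repetition, repeat
# runs by literal motif matching, ORFs by per-ATG scanning, and PCR sites by
# position-wise string comparison.

# Primitivity by direct check of every proper divisor.
oracle_is_primitive <- function(motif) {
  k <- nchar(motif)
  if (k == 1) return(TRUE)
  divs <- which(k %% seq_len(k - 1) == 0)
  for (d in divs) {
    if (paste(rep(substr(motif, 1, d), k / d), collapse = "") == motif) {
      return(FALSE)
    }
  }
  TRUE
}

# All primitive k-mers by filtering the full k-mer set.
oracle_primitive_motifs <- function(k) {
  kmers <- "";
  for (i in seq_len(k)) {
    kmers <- as.vector(outer(kmers, c("A", "C", "G", "T"), paste0))
  }
  sort(kmers[vapply(kmers, oracle_is_primitive, logical(1))])
}

# Brute-force SSR finder: for every start and motif length, count full motif
# copies by literal matching, keep left-maximal runs of full-period length
# >= min_len with a primitive motif, then drop runs nested inside another.
oracle_find_ssrs <- function(seq, seq_id = "seq", min_len = 18) {
  n <- nchar(seq)
  out <- list()
  for (k in 1:6) {
    for (i in seq_len(max(0, n - min_len + 1))) {
      motif <- substr(seq, i, i + k - 1)
      if (nchar(motif) < k || grepl("N", motif, fixed = TRUE)) next
      if (!oracle_is_primitive(motif)) next
      # left-maximality: the preceding base must break the periodicity
      if (i > 1) {
        prev <- substr(seq, i - 1, i - 1)
        if (prev != "N" && prev == substr(motif, k, k)) next
      }
      m <- 1
      while (substr(seq, i + m * k, i + m * k + k - 1) == motif) m <- m + 1
      if (m * k < min_len) next
      out[[length(out) + 1]] <- data.frame(
        seq_id = seq_id, motif = motif, motif_len = k,
        repeat_count = m, start = i - 1L,
        end = i - 1L + m * k, length = m * k
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(seq_id = character(), motif = character(),
                      motif_len = integer(), repeat_count = integer(),
                      start = integer(), end = integer(), length = integer()))
  }
  df <- do.call(rbind, out)
  nested <- vapply(seq_len(nrow(df)), function(r) {
    any(df$start <= df$start[r] & df$end >= df$end[r] &
          (df$start < df$start[r] | df$end > df$end[r]))
  }, logical(1))
  df <- df[!nested, , drop = FALSE]
  df <- df[order(df$start, df$motif_len), ]
  rownames(df) <- NULL
  df
}

# Test sequences that actually exercise the miner: uniform background with
# occasional low-complexity patches and tandem insertions straddling the
# detection threshold.
random_testing_sequence <- function(len = 300) {
  pieces <- character(0)
  remaining <- len
  while (remaining > 0) {
    what <- sample(c("bg", "at_rich", "tandem"), 1, prob = c(0.5, 0.2, 0.3))
    if (what == "bg") {
      take <- min(remaining, sample(20:60, 1))
      pieces <- c(pieces, paste(sample(c("A", "C", "G", "T"), take,
                                       replace = TRUE), collapse = ""))
    } else if (what == "at_rich") {
      take <- min(remaining, sample(10:30, 1))
      pieces <- c(pieces, paste(sample(c("A", "T"), take, replace = TRUE),
                                collapse = ""))
    } else {
      k <- sample(1:6, 1)
      motif <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                     collapse = "")
      reps <- sample(2:12, 1)
      ins <- strrep(motif, reps)
      take <- min(remaining, nchar(ins))
      pieces <- c(pieces, substr(ins, 1, take))
    }
    remaining <- len - sum(nchar(pieces))
  }
  substr(paste(pieces, collapse = ""), 1, len)
}

# Brute-force longest-ORF finder: scan from every ATG in all six frames.
oracle_longest_orf <- function(seq, min_aa = 30) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc(seq)
    n <- nchar(s)
    for (i in seq_len(max(0, n - 5))) {
      if (substr(s, i, i + 2) != "ATG") next
      j <- i + 3
      while (j + 2 <= n) {
        cod <- substr(s, j, j + 2)
        if (cod %in% stops) break
        j <- j + 3
      }
      if (j + 2 > n) next # no stop inside the sequence
      len_aa <- (j - i) / 3
      if (len_aa < min_aa) next
      cand <- list(start = i - 1L, end = j + 2L, strand = strand,
                   frame = (i - 1L) %% 3L, length_aa = len_aa)
      span <- cand$end - cand$start
      if (is.null(best) || span > (best$end - best$start) ||
          (span == (best$end - best$start) &&
           ((cand$strand == "+" && best$strand == "-") ||
            (cand$strand == best$strand && cand$start < best$start)))) {
        best <- cand
      }
    }
  }
  best
}

# Brute-force in-silico PCR: literal scanning for all plus-strand sites of
# each primer and each primer's reverse complement, then enumeration of
# inward-facing pairs within the product bound.
oracle_pcr <- function(chrom_seq, chrom_name, fwd, rev, max_product = 2000) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  sites <- function(p) {
    n <- nchar(chrom_seq); L <- nchar(p)
    which(vapply(seq_len(max(0, n - L + 1)),
                 function(i) substr(chrom_seq, i, i + L - 1) == p, logical(1)))
  }
  out <- list()
  combos <- list(list(l = fwd, r = rc(rev), o = "fwd_plus"),
                 list(l = rev, r = rc(fwd), o = "rev_plus"))
  for (cb in combos) {
    ls <- sites(cb$l); rs <- sites(cb$r)
    for (i in ls) {
      for (j in rs) {
        if (j < i) next
        prod <- j + nchar(cb$r) - i
        if (prod > max_product || prod < max(nchar(cb$l), nchar(cb$r))) next
        out[[length(out) + 1]] <- data.frame(
          chrom = chrom_name, start = i - 1L, end = i - 1L + prod,
          product_len = prod, orientation = cb$o
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      product_len = integer(), orientation = character()))
  }
  df <- unique(do.call(rbind, out))
  df <- df[order(df$chrom, df$start, df$end), ]
  rownames(df) <- NULL
  df
}

# Direct Benjamini-Hochberg step-up: adj_(i) = min_{j >= i} m * p_(j) / j,
# capped at 1, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * ranked[i] / i)
    adj[i] <- min(1, running)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}
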
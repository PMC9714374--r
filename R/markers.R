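#' Read an accession-by-marker genotype table
#'
#' Expects a CSV with one row per accession: the first column holds accession
#' labels, an optional `group` column holds group tags (e.g. cultivated vs
#' wild), and the remaining columns hold integer allele calls with empty
#' cells or `NA` for missing calls.
#'
#' @param path CSV file path.
#' @return Tibble with `accession`, `group` (possibly `NA`) and one integer
#'   column per marker.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "accession"
  if (!"group" %in% names(df)) df$group <- NA_character_
  marker_cols <- setdiff(names(df), c("accession", "group"))
  df[marker_cols] <- lapply(df[marker_cols], as.integer)
  tibble::as_tibble(df[, c("accession", "group", marker_cols)])
}

genotype_calls <- function(gm) {
  marker_cols <- setdiff(names(gm), c("accession", "group"))
  m <- as.matrix(gm[, marker_cols])
  storage.mode(m) <- "integer"
  rownames(m) <- gm$accession
  m
}

#' Score marker polymorphism
#'
#' A marker is polymorphic when it shows at least two distinct non-missing
#' allele calls across the scored accessions. The headline rate uses an
#' explicit denominator because marker panels are quoted against different
#' baselines (pairs designed vs pairs that amplified); it is never inferred.
#'
#' @param gm Genotype tibble (as from [read_genotypes()] or
#'   [gen_genotypes()]`$genotypes`).
#' @param accessions Optional character vector restricting scoring to a
#'   subset of accessions (e.g. only the cultivated group).
#' @param denominator Denominator of the polymorphism rate; defaults to the
#'   number of markers in `gm`.
#' @return A list of class `ssr_polymorphism` with `markers` (tibble:
#'   `marker`, `n_alleles`, `polymorphic`), `n_polymorphic`, `n_markers`,
#'   `denominator` and `rate` (percent, half-up to 1 decimal).
#' @export
score_polymorphism <- function(gm, accessions = NULL, denominator = NULL) {
  calls <- genotype_calls(gm)
  if (!is.null(accessions)) {
    missing_acc <- setdiff(accessions, rownames(calls))
    if (length(missing_acc) > 0) {
      stop("unknown accession(s): ", paste(missing_acc, collapse = ", "),
           call. = FALSE)
    }
    calls <- calls[accessions, , drop = FALSE]
  }
  if (nrow(calls) == 0) stop("no accessions to score", call. = FALSE)
  n_alleles <- apply(calls, 2, function(x) length(unique(x[!is.na(x)])))
  markers <- tibble::tibble(
    marker = colnames(calls),
    n_alleles = as.integer(n_alleles),
    polymorphic = n_alleles >= 2
  )
  denominator <- denominator %||% ncol(calls)
  if (denominator < 1) stop("`denominator` must be >= 1", call. = FALSE)
  structure(
    list(
      markers = markers,
      n_polymorphic = sum(markers$polymorphic),
      n_markers = ncol(calls),
      denominator = as.integer(denominator),
      rate = round_half_up(100 * sum(markers$polymorphic) / denominator, 1)
    ),
    class = "ssr_polymorphism"
  )
}

#' @export
print.ssr_polymorphism <- function(x, ...) {
  cat(sprintf("%d of %d markers polymorphic; rate %.1f%% (denominator %d)\n",
              x$n_polymorphic, x$n_markers, x$rate, x$denominator))
  invisible(x)
}

#' Standardize matrix rows to Z-scores
#'
#' Centres and scales each row to mean 0 and (sample) standard deviation 1.
#' Rows with no spread cannot be standardized; they are set to 0 and their
#' indices recorded in the `constant_rows` attribute.
#'
#' @param m Numeric matrix.
#' @return Matrix of the same shape; see Details for constant rows.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m, na.rm = TRUE)
  sdv <- apply(m, 1, stats::sd, na.rm = TRUE)
  const <- which(is.na(sdv) | sdv == 0)
  sdv[const] <- 1
  out <- sweep(sweep(m, 1, mu, "-"), 1, sdv, "/")
  out[const, ] <- 0
  attr(out, "constant_rows") <- as.integer(const)
  out
}

# One-hot encode allele calls: one binary column per observed (marker, allele)
# pair; missing calls give NA across the marker's block.
one_hot_calls <- function(calls) {
  blocks <- lapply(colnames(calls), function(mk) {
    x <- calls[, mk]
    alleles <- sort(unique(x[!is.na(x)]))
    if (length(alleles) == 0) return(NULL)
    b <- vapply(alleles, function(a) as.numeric(x == a), numeric(nrow(calls)))
    colnames(b) <- paste0(mk, ":", alleles)
    b
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- rownames(calls)
  out
}

#' Two-sided clustering of a genotype matrix
#'
#' Hierarchical clustering of accessions and markers, the computational core
#' of a genotype heatmap. Accession distances are Euclidean distances between
#' row-standardized one-hot encodings of the allele calls (so results do not
#' depend on how alleles are numbered); marker distances are Euclidean
#' distances between columns of the row-standardized numeric call matrix.
#' Markers missing in more than half the accessions are dropped with a
#' warning. Cutting the accession tree at `k` groups gives the group
#' assignment.
#'
#' @param gm Genotype tibble.
#' @param k Number of accession groups to cut (default 2).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return A list of class `ssr_biclust` with `accession_hclust`,
#'   `marker_hclust` (or `NULL` with a single marker), `matrix` (the
#'   row-standardized call matrix, rows/columns in dendrogram order),
#'   `groups` (named integer vector) and `dropped_markers`.
#' @export
bicluster <- function(gm, k = 2, linkage = "complete") {
  calls <- genotype_calls(gm)
  if (nrow(calls) < 2) {
    return(structure(list(
      accession_hclust = NULL, marker_hclust = NULL,
      matrix = zscore_rows(calls),
      groups = stats::setNames(rep(1L, nrow(calls)), rownames(calls)),
      dropped_markers = character(0)
    ), class = "ssr_biclust"))
  }
  miss <- colMeans(is.na(calls))
  dropped <- colnames(calls)[miss > 0.5]
  if (length(dropped) > 0) {
    warning("dropping marker(s) missing in >50% of accessions: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    calls <- calls[, miss <= 0.5, drop = FALSE]
  }
  if (ncol(calls) < 1) stop("no markers left to cluster", call. = FALSE)
  oh <- one_hot_calls(calls)
  acc_d <- stats::dist(zscore_rows(oh))
  acc_d[is.na(acc_d)] <- max(acc_d, na.rm = TRUE)
  acc_hc <- stats::hclust(acc_d, method = linkage)
  z <- zscore_rows(calls)
  marker_hc <- NULL
  if (ncol(z) >= 2) {
    mk_d <- stats::dist(t(z))
    mk_d[is.na(mk_d)] <- max(c(0, mk_d), na.rm = TRUE)
    marker_hc <- stats::hclust(mk_d, method = linkage)
  }
  groups <- stats::cutree(acc_hc, k = min(k, nrow(calls)))
  ord_rows <- acc_hc$order
  ord_cols <- if (is.null(marker_hc)) seq_len(ncol(z)) else marker_hc$order
  structure(list(
    accession_hclust = acc_hc,
    marker_hclust = marker_hc,
    matrix = z[ord_rows, ord_cols, drop = FALSE],
    groups = groups,
    dropped_markers = dropped
  ), class = "ssr_biclust")
}

#' @export
print.ssr_biclust <- function(x, ...) {
  cat(sprintf("Two-sided genotype clustering: %d accessions x %d markers, %d groups\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$groups))))
  invisible(x)
}

#' Export biclustering dendrograms as newick strings
#'
#' @param bc An `ssr_biclust` object.
#' @return Named character vector with `accessions` and (when present)
#'   `markers` newick strings.
#' @export
export_newick <- function(bc) {
  stopifnot(inherits(bc, "ssr_biclust"))
  out <- character(0)
  if (!is.null(bc$accession_hclust)) {
    out["accessions"] <- ape::write.tree(ape::as.phylo(bc$accession_hclust))
  }
  if (!is.null(bc$marker_hclust)) {
    out["markers"] <- ape::write.tree(ape::as.phylo(bc$marker_hclust))
  }
  out
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between a predicted grouping and truth labels, corrected for
#' chance: 1 for identical partitions, about 0 for independent ones.
#' Computed in closed form from the pair-counting contingency table.
#'
#' @param predicted,truth Vectors of group labels over the same items.
#' @return The adjusted Rand index, a number in `[-1, 1]`.
#' @export
group_concordance <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` must have the same length", call. = FALSE)
  }
  tab <- table(predicted, truth)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  a <- sum(comb2(rowSums(tab)))
  b <- sum(comb2(colSums(tab)))
  n <- comb2(length(predicted))
  expected <- a * b / n
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
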
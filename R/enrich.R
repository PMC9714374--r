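#' Hypergeometric over-representation test with BH adjustment
#'
#' Tests each annotation term for over-representation in a selected gene set.
#' For a term annotating `K` of the `N` universe genes, with `n` genes
#' selected and `k` of them annotated, the raw p-value is the upper tail
#' `P[X >= k]` of the hypergeometric distribution; p-values are adjusted
#' across all tested terms by the Benjamini-Hochberg step-up procedure, and
#' terms are called significant below `alpha` (default 0.05) on the adjusted
#' scale. Terms with zero overlap get `p = 1`.
#'
#' @param selected Character vector of selected gene ids; must be a subset of
#'   the universe.
#' @param annotation Tibble with `gene_id` and `term_id` columns (one row per
#'   gene-term link).
#' @param universe Optional character vector of universe gene ids; defaults
#'   to all genes in `annotation`.
#' @param alpha Significance threshold on the adjusted p-value.
#' @return A tibble of class `ssr_enrichment`, one row per term, sorted by
#'   adjusted then raw p-value: `term_id`, `overlap` (k), `term_size` (K),
#'   `selected_size` (n), `universe_size` (N), `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
#' @examples
#' ann <- tibble::tibble(gene_id = paste0("g", 1:20), term_id = rep("T1", 20))
#' hypergeom_enrichment(paste0("g", 1:5), ann)
hypergeom_enrichment <- function(selected, annotation, universe = NULL,
                                 alpha = 0.05) {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotation)))
  selected <- unique(selected)
  universe <- unique(universe %||% annotation$gene_id)
  if (!all(annotation$gene_id %in% universe)) {
    stop("annotation contains genes outside the universe", call. = FALSE)
  }
  outside <- setdiff(selected, universe)
  if (length(outside) > 0) {
    stop("selected gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(selected)
  terms <- split(unique(annotation[, c("gene_id", "term_id")])$gene_id,
                 unique(annotation[, c("gene_id", "term_id")])$term_id)
  res <- purrr::imap(terms, function(genes, tid) {
    K <- length(genes)
    k <- length(intersect(genes, selected))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(term_id = tid, overlap = k, term_size = K,
                   selected_size = n, universe_size = N, p_value = p)
  })
  out <- dplyr::bind_rows(res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted < alpha
  out <- dplyr::arrange(out, .data$p_adjusted, .data$p_value, .data$term_id)
  class(out) <- c("ssr_enrichment", class(out))
  attr(out, "alpha") <- alpha
  out
}
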
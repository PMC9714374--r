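#' Tidy a polymorphism report
#'
#' @param x An `ssr_polymorphism` object.
#' @param ... Unused.
#' @return The per-marker tibble (`marker`, `n_alleles`, `polymorphic`).
#' @method tidy ssr_polymorphism
#' @export
tidy.ssr_polymorphism <- function(x, ...) {
  x$markers
}

#' One-row summary of a polymorphism report
#'
#' @param x An `ssr_polymorphism` object.
#' @param ... Unused.
#' @return Tibble with `n_polymorphic`, `n_markers`, `denominator`, `rate`.
#' @method glance ssr_polymorphism
#' @export
glance.ssr_polymorphism <- function(x, ...) {
  tibble::tibble(n_polymorphic = x$n_polymorphic, n_markers = x$n_markers,
                 denominator = x$denominator, rate = x$rate)
}

#' Tidy a biclustering result
#'
#' @param x An `ssr_biclust` object.
#' @param ... Unused.
#' @return Tibble with `accession` and its `group` at the configured cut.
#' @method tidy ssr_biclust
#' @export
tidy.ssr_biclust <- function(x, ...) {
  tibble::tibble(accession = names(x$groups), group = unname(x$groups))
}

#' One-row summary of a biclustering result
#'
#' @param x An `ssr_biclust` object.
#' @param ... Unused.
#' @return Tibble with dimensions, group count and dropped-marker count.
#' @method glance ssr_biclust
#' @export
glance.ssr_biclust <- function(x, ...) {
  tibble::tibble(
    n_accessions = nrow(x$matrix),
    n_markers = ncol(x$matrix),
    n_groups = length(unique(x$groups)),
    n_dropped_markers = length(x$dropped_markers)
  )
}

#' Tidy an enrichment result
#'
#' @param x An `ssr_enrichment` object.
#' @param ... Unused.
#' @return A plain tibble of the per-term results.
#' @method tidy ssr_enrichment
#' @export
tidy.ssr_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ssr_enrichment")
  out
}

#' One-row summary of an enrichment result
#'
#' @param x An `ssr_enrichment` object.
#' @param ... Unused.
#' @return Tibble with term counts and the significance threshold used.
#' @method glance ssr_enrichment
#' @export
glance.ssr_enrichment <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha")
  )
}
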
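#' Plot the per-type and repeat-number distributions of an SSR survey
#'
#' @param object An `ssr_summary` object from [summarize_ssrs()].
#' @param which `"type"` for motif-type shares or `"repeats"` for the
#'   repeat-number bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ssr_summary
#' @export
autoplot.ssr_summary <- function(object, which = c("type", "repeats"), ...) {
  which <- match.arg(which)
  if (which == "type") {
    df <- object$type_table
    df$type <- factor(df$type, levels = df$type)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$count)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percent)),
                         vjust = -0.3, size = 3) +
      ggplot2::labs(x = NULL, y = "SSRs",
                    title = "SSR frequency by motif type") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  } else {
    df <- object$repeat_bins
    df$bin <- factor(df$bin, levels = df$bin)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$count)) +
      ggplot2::geom_col(fill = "darkorange") +
      ggplot2::labs(x = "repeat number", y = "SSRs",
                    title = "Repeat-number distribution") +
      ggplot2::theme_minimal()
  }
}

#' Heatmap of a two-sided genotype clustering
#'
#' Tile heatmap of the row-standardized genotype matrix with rows and columns
#' in dendrogram order, the display half of a genotype heatmap analysis.
#'
#' @param object An `ssr_biclust` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ssr_biclust
#' @export
autoplot.ssr_biclust <- function(object, ...) {
  m <- object$matrix
  df <- tibble::as_tibble(m, rownames = "accession") |>
    tidyr::pivot_longer(-"accession", names_to = "marker", values_to = "z")
  df$accession <- factor(df$accession, levels = rownames(m))
  df$marker <- factor(df$marker, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$marker, y = .data$accession,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "black", high = "green",
                                  name = "Z score") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Two-sided clustering of genotype calls") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       size = 6))
}

#' Bar chart of enrichment results
#'
#' @param object An `ssr_enrichment` object.
#' @param top Number of top terms (by adjusted p) to show.
#' @param ... Unused.
#' @return A ggplot of `-log10` adjusted p-values.
#' @method autoplot ssr_enrichment
#' @export
autoplot.ssr_enrichment <- function(object, top = 15, ...) {
  df <- utils::head(tidy(object), top)
  df$term_id <- factor(df$term_id, levels = rev(df$term_id))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_adjusted),
                                   y = .data$term_id,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL,
                  title = "Term over-representation") +
    ggplot2::theme_minimal()
}

#' Physical map plot of mapped markers
#'
#' Draws each chromosome as a vertical bar with marker positions (in Mbp)
#' ticked along it.
#'
#' @param bed BED tibble (`chrom`, `start`, `end`, `name`), e.g. from
#'   [write_physical_map()].
#' @return A ggplot.
#' @export
plot_physical_map <- function(bed) {
  df <- map_positions_mbp(bed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom, y = .data$pos_mbp)) +
    ggplot2::geom_point(shape = 95, size = 6, colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), hjust = -0.15,
                       size = 2.5) +
    ggplot2::labs(x = NULL, y = "position (Mbp)",
                  title = "Physical positions of SSR markers") +
    ggplot2::theme_minimal()
}
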
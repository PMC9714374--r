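TYPE_LABELS <- c("mononucleotide", "dinucleotide", "trinucleotide",
                 "tetranucleotide", "pentanucleotide", "hexanucleotide")

#' Per-type SSR frequency table
#'
#' Counts detected SSRs by motif length (mono- to hexanucleotide) and gives
#' each type's share of the grand total, rounded half-up to 2 decimals.
#'
#' @param records SSR record tibble from [find_ssrs()].
#' @return Tibble with `motif_len`, `type`, `count`, `percent`. All six types
#'   are always present; with no records, counts are 0 and percents `NA`.
#' @export
type_frequency_table <- function(records) {
  counts <- vapply(1:6, function(k) sum(records$motif_len == k), integer(1))
  total <- sum(counts)
  tibble::tibble(
    motif_len = 1:6,
    type = TYPE_LABELS,
    count = counts,
    percent = if (total == 0) NA_real_ else round_half_up(100 * counts / total, 2)
  )
}

#' Motif frequency table within each repeat type
#'
#' Counts records per motif within each motif length, with each motif's share
#' of its type's total (rounded half-up to 1 decimal), sorted by descending
#' count. Grouping by `"motif"` keeps literal phased motifs distinct (so `TC`
#' and its reverse complement `AG` are separate rows, as on an SSR survey
#' table); grouping by `"class"` merges rotations of the same motif on the
#' same strand (`TC` with `CT`) but never merges reverse complements.
#'
#' @param records SSR record tibble.
#' @param group_by `"motif"` (literal, as phased) or `"class"` (minimal
#'   rotation).
#' @return Tibble with `motif_len`, `motif`, `count`, `percent`.
#' @export
motif_frequency_table <- function(records, group_by = c("motif", "class")) {
  group_by <- match.arg(group_by)
  key <- if (group_by == "motif") records$motif else records$motif_class
  df <- tibble::tibble(motif_len = records$motif_len, motif = key)
  out <- df |>
    dplyr::count(.data$motif_len, .data$motif, name = "count") |>
    dplyr::group_by(.data$motif_len) |>
    dplyr::mutate(percent = round_half_up(100 * .data$count / sum(.data$count), 1)) |>
    dplyr::arrange(.data$motif_len, dplyr::desc(.data$count), .data$motif) |>
    dplyr::ungroup()
  out
}

#' Repeat-number distribution
#'
#' Bins records by repeat number. Default bins are the half-open integer
#' partition `[3,9]`, `[10,15]`, `[16,20]`, `[21,Inf)`: published tables of
#' this kind often print overlapping bin labels ("3-9", "10-15", "15-20",
#' ">20"); a partition is used here so every record falls in exactly one bin.
#'
#' @param records SSR record tibble; all repeat counts must be >= 3.
#' @param breaks Increasing integer vector of lower bin edges.
#' @return Tibble with `bin`, `count`, `percent` (half-up, 1 decimal).
#' @export
repeat_number_distribution <- function(records, breaks = c(3L, 10L, 16L, 21L)) {
  if (nrow(records) > 0 && any(records$repeat_count < 3)) {
    stop("repeat counts below 3 are inconsistent with the minimum-length rule",
         call. = FALSE)
  }
  lo <- breaks
  hi <- c(breaks[-1] - 1L, Inf)
  labels <- ifelse(is.finite(hi), paste0(lo, "-", hi), paste0(">=", lo))
  counts <- vapply(seq_along(lo), function(i) {
    sum(records$repeat_count >= lo[i] & records$repeat_count <= hi[i])
  }, integer(1))
  total <- sum(counts)
  tibble::tibble(
    bin = labels,
    count = counts,
    percent = if (total == 0) NA_real_ else round_half_up(100 * counts / total, 1)
  )
}

#' Distribution of SSRs across cDNA clones and corpus incidence
#'
#' For each repeat type, counts the distinct cDNAs harboring at least one SSR
#' of that type, the share of that type's SSRs accounted for by those cDNAs
#' (`percent = 100 * n_cdnas / n_ssrs`), and how many of those cDNAs carry
#' exactly one vs more than one SSR of the type. Incidence is reported on the
#' screened-corpus denominator, which must be supplied (such surveys quote
#' slightly different corpus sizes in different places, so it is never
#' inferred): `incidence_ssr` is the headline figure, SSR regions per 100
#' screened sequences; `incidence_cdna` is the percent of screened sequences
#' harboring at least one SSR.
#'
#' @param records SSR record tibble.
#' @param n_screened Number of sequences screened (>= number of distinct
#'   `seq_id`s in `records`).
#' @return A list with `cdna_table` (tibble: `motif_len`, `type`, `n_ssrs`,
#'   `n_cdnas`, `percent`, `n_single`, `n_multi`) and `incidence` (tibble:
#'   `n_ssrs`, `n_cdnas`, `n_screened`, `incidence_ssr`, `incidence_cdna`).
#' @export
cdna_distribution <- function(records, n_screened) {
  n_distinct_ids <- dplyr::n_distinct(records$seq_id)
  if (n_screened < n_distinct_ids) {
    stop("`n_screened` is smaller than the number of distinct sequences with SSRs",
         call. = FALSE)
  }
  per_type <- lapply(1:6, function(k) {
    rk <- records[records$motif_len == k, ]
    per_cdna <- table(rk$seq_id)
    tibble::tibble(
      motif_len = k,
      type = TYPE_LABELS[k],
      n_ssrs = nrow(rk),
      n_cdnas = length(per_cdna),
      percent = if (nrow(rk) == 0) NA_real_ else
        round_half_up(100 * length(per_cdna) / nrow(rk), 1),
      n_single = sum(per_cdna == 1),
      n_multi = sum(per_cdna > 1)
    )
  })
  incidence <- tibble::tibble(
    n_ssrs = nrow(records),
    n_cdnas = n_distinct_ids,
    n_screened = as.integer(n_screened),
    incidence_ssr = round_half_up(100 * nrow(records) / n_screened, 2),
    incidence_cdna = round_half_up(100 * n_distinct_ids / n_screened, 2)
  )
  list(cdna_table = dplyr::bind_rows(per_type), incidence = incidence)
}

#' Perfect/imperfect tallies per repeat type
#'
#' @param records SSR record tibble with the `perfect` flag set.
#' @return Tibble with one row per motif length plus a `total` row:
#'   `type`, `n_imperfect`, `n_perfect`, `count`.
#' @export
perfection_table <- function(records) {
  rows <- lapply(1:6, function(k) {
    rk <- records[records$motif_len == k, ]
    tibble::tibble(
      type = TYPE_LABELS[k],
      n_imperfect = sum(!rk$perfect),
      n_perfect = sum(rk$perfect),
      count = nrow(rk)
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::bind_rows(out, tibble::tibble(
    type = "total",
    n_imperfect = sum(out$n_imperfect),
    n_perfect = sum(out$n_perfect),
    count = sum(out$count)
  ))
}

#' All descriptive summaries in one call
#'
#' Convenience wrapper producing the full set of survey tables from one SSR
#' record tibble.
#'
#' @inheritParams cdna_distribution
#' @return A list of class `ssr_summary` with elements `type_table`,
#'   `motif_table`, `repeat_bins`, `cdna_table`, `incidence`,
#'   `perfection_table`.
#' @export
summarize_ssrs <- function(records, n_screened) {
  cd <- cdna_distribution(records, n_screened)
  structure(
    list(
      type_table = type_frequency_table(records),
      motif_table = motif_frequency_table(records),
      repeat_bins = repeat_number_distribution(records),
      cdna_table = cd$cdna_table,
      incidence = cd$incidence,
      perfection_table = perfection_table(records)
    ),
    class = "ssr_summary"
  )
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat("SSR survey summary\n")
  cat(sprintf("  %d SSRs in %d of %d screened sequences (%.2f%% SSR incidence)\n",
              x$incidence$n_ssrs, x$incidence$n_cdnas, x$incidence$n_screened,
              x$incidence$incidence_ssr))
  print(x$type_table, ...)
  invisible(x)
}
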
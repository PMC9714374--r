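# Build a record tibble with prescribed per-type structure. `spec` is a list
# of lists: motif, n (records), and optionally ids (host sequence ids) and
# repeat_count / perfect overrides.
make_records <- function(spec) {
  rows <- lapply(spec, function(x) {
    k <- nchar(x$motif)
    n <- x$n
    rc <- x$repeat_count %||% max(3L, ceiling(18 / k))
    len <- k * rc
    tibble::tibble(
      seq_id = x$ids %||% paste0("s", seq_len(n), "_", x$motif),
      motif = x$motif,
      motif_class = x$motif,
      motif_len = k,
      repeat_count = as.integer(rc),
      start = 0L, end = as.integer(len), length = as.integer(len),
      perfect = x$perfect %||% (len >= 20)
    )
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The per-type structure of a published safflower cDNA survey, used as a
# fixed arithmetic fixture: counts 7/405/658/128/98/545.
survey_counts <- c(7L, 405L, 658L, 128L, 98L, 545L)
survey_motifs <- c("T", "TC", "TTC", "TTTG", "TTCTC", "TCCATC")
survey_records <- make_records(purrr::map2(
  survey_motifs, survey_counts, function(m, n) list(motif = m, n = n)
))

test_that("type frequency shares reproduce printed survey percentages", {
  tt <- type_frequency_table(survey_records)
  expect_equal(sum(tt$count), 1841L)
  expect_equal(tt$count, survey_counts)
  expect_equal(tt$percent, c(0.38, 22.00, 35.74, 6.95, 5.32, 29.60))
  # percents sum to 100 within rounding slack
  expect_lt(abs(sum(tt$percent) - 100), 0.1 * 6)
})

test_that("type table handles empty and single-record input without division errors", {
  empty <- survey_records[0, ]
  tt <- type_frequency_table(empty)
  expect_equal(tt$count, rep(0L, 6))
  expect_true(all(is.na(tt$percent)))
  one <- survey_records[survey_records$motif_len == 3, ][1, ]
  tt1 <- type_frequency_table(one)
  expect_equal(tt1$percent[3], 100)
  expect_equal(sum(tt1$count), 1L)
})

test_that("dinucleotide motif shares match the printed table arithmetic", {
  recs <- make_records(list(
    list(motif = "TC", n = 228), list(motif = "AG", n = 83),
    list(motif = "AC", n = 66), list(motif = "GT", n = 28)
  ))
  mt <- motif_frequency_table(recs)
  expect_equal(mt$percent[mt$motif == "TC"], 56.3)
  expect_equal(mt$percent[mt$motif == "AG"], 20.5)
  expect_equal(mt$percent[mt$motif == "AC"], 16.3)
  expect_equal(mt$count[1], 228L) # sorted descending within type
})

test_that("class grouping merges rotations but never reverse complements", {
  recs <- make_records(list(
    list(motif = "TC", n = 5), list(motif = "CT", n = 3),
    list(motif = "AG", n = 2)
  ))
  recs$motif_class <- vapply(recs$motif, function(m) {
    cdnassr:::minimal_rotation(m)
  }, character(1))
  by_class <- motif_frequency_table(recs, group_by = "class")
  expect_equal(by_class$count[by_class$motif == "CT"], 8L) # TC + CT
  expect_equal(by_class$count[by_class$motif == "AG"], 2L) # untouched
  by_motif <- motif_frequency_table(recs, group_by = "motif")
  expect_equal(sort(by_motif$count), c(2L, 3L, 5L))
})

test_that("repeat-number bins partition records at the documented edges", {
  recs <- make_records(lapply(c(3, 9, 10, 15, 16, 20, 21, 28), function(rc) {
    list(motif = "TCCATC", n = 1, repeat_count = rc)
  }))
  rb <- repeat_number_distribution(recs)
  expect_equal(rb$count, c(2L, 2L, 2L, 2L))
  expect_equal(sum(rb$percent), 100)

  all5 <- make_records(list(list(motif = "TTTG", n = 10, repeat_count = 5)))
  rb5 <- repeat_number_distribution(all5)
  expect_equal(rb5$percent[1], 100)

  bad <- make_records(list(list(motif = "TCCATC", n = 1, repeat_count = 2)))
  expect_error(repeat_number_distribution(bad), "below 3")
})

test_that("cDNA distribution reproduces the printed per-type and incidence arithmetic", {
  # hexanucleotides: 545 SSRs over 422 distinct cDNAs -> 77.4% ;
  # build 341 single-SSR cDNAs and 81 cDNAs hosting the remaining 204
  multi_ids <- rep(paste0("m", 1:81), length.out = 204)
  hexa <- make_records(list(
    list(motif = "TCCATC", n = 341, ids = paste0("s", 1:341)),
    list(motif = "TCCATC", n = 204, ids = multi_ids)
  ))
  cd <- cdna_distribution(hexa, n_screened = 39817)
  hrow <- cd$cdna_table[cd$cdna_table$motif_len == 6, ]
  expect_equal(hrow$n_ssrs, 545L)
  expect_equal(hrow$n_cdnas, 422L)
  expect_equal(hrow$percent, 77.4)
  expect_equal(hrow$n_single + hrow$n_multi, hrow$n_cdnas)
  expect_equal(hrow$n_single, 341L)
  expect_equal(hrow$n_multi, 81L)

  # 1,841 SSRs over 1,667 cDNAs screened against 39,817 sequences -> 4.62%
  ids <- c(paste0("c", 1:1493), rep(paste0("d", 1:174), each = 2))
  recs <- make_records(list(list(motif = "TTC", n = 1841, ids = ids)))
  inc <- cdna_distribution(recs, n_screened = 39817)$incidence
  expect_equal(inc$n_ssrs, 1841L)
  expect_equal(inc$n_cdnas, 1667L)
  expect_equal(inc$incidence_ssr, 4.62)

  # one cDNA with two SSRs of one type
  two <- make_records(list(list(motif = "TTC", n = 2, ids = c("x", "x"))))
  t2 <- cdna_distribution(two, n_screened = 10)$cdna_table
  row <- t2[t2$motif_len == 3, ]
  expect_equal(row$n_cdnas, 1L)
  expect_equal(row$n_multi, 1L)
  expect_equal(row$n_single, 0L)

  expect_error(cdna_distribution(two, n_screened = 0), "smaller")
})

test_that("perfection tallies and their column sums match the printed table", {
  spec <- list(
    list(motif = "T", n = 7, perfect = TRUE),
    list(motif = "TC", n = 401, perfect = TRUE),
    list(motif = "TC", n = 4, perfect = FALSE),
    list(motif = "TTC", n = 658, perfect = TRUE),
    list(motif = "TTTG", n = 128, perfect = TRUE),
    list(motif = "TTCTC", n = 98, perfect = TRUE),
    list(motif = "TCCATC", n = 142, perfect = TRUE),
    list(motif = "TCCATC", n = 403, perfect = FALSE)
  )
  pt <- perfection_table(make_records(spec))
  total <- pt[pt$type == "total", ]
  expect_equal(total$n_perfect, 1434L)
  expect_equal(total$n_imperfect, 407L)
  expect_equal(pt$n_imperfect[pt$type == "dinucleotide"], 4L)
  expect_equal(pt$n_imperfect[pt$type == "hexanucleotide"], 403L)
  # hexanucleotide imperfect fraction ~74%
  hexa <- pt[pt$type == "hexanucleotide", ]
  expect_equal(round(100 * hexa$n_imperfect / hexa$count), 74)

  all_perfect <- make_records(list(list(motif = "TTC", n = 5, repeat_count = 7)))
  pt2 <- perfection_table(all_perfect)
  expect_true(all(pt2$n_imperfect == 0))
})

test_that("partition identities hold on random synthetic corpora", {
  for (s in 1:10) {
    cfg <- synth_config(n_sequences = 8, length_range = c(300L, 600L),
                        ssr_density = 1.5, seed = 400 + s)
    recs <- find_ssrs(gen_cdna_corpus(cfg)$sequences)
    if (nrow(recs) == 0) next
    summ <- summarize_ssrs(recs, n_screened = 8)
    expect_equal(sum(summ$type_table$count), nrow(recs))
    expect_lt(abs(sum(summ$type_table$percent) - 100), 0.6)
    expect_equal(sum(summ$repeat_bins$count), nrow(recs))
    per <- summ$perfection_table
    expect_equal(per$n_imperfect + per$n_perfect, per$count)
    cd <- summ$cdna_table
    expect_equal(cd$n_single + cd$n_multi, cd$n_cdnas)
    mt <- summ$motif_table |>
      dplyr::group_by(motif_len) |>
      dplyr::summarise(n = sum(count))
    expect_equal(sum(mt$n), nrow(recs))
  }
})

test_that("half-up rounding is bit-stable where banker's rounding would flip", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(0.135, 2), 0.14)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
})
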
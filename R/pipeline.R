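#' Pipeline configuration
#'
#' Collects the inputs and thresholds of [run_all()]. All thresholds default
#' to the conventions used throughout the package: detection at 18 nt,
#' perfection at 20 nt, adjusted p < 0.05.
#'
#' @param fasta cDNA FASTA path (required).
#' @param genome Genome FASTA path; when given, the mapping stage runs.
#' @param genotypes Genotype CSV path; when given, the marker stage runs.
#' @param annotation Gene-to-term TSV path (columns `gene_id`, `term_id`).
#' @param selected Path to a text file of selected gene ids (one per line);
#'   with `annotation`, the enrichment stage runs.
#' @param universe Optional path to a text file of universe gene ids;
#'   defaults to the genes in `annotation`.
#' @param n_screened Incidence denominator; defaults to the number of
#'   sequences in `fasta`.
#' @param min_len,perfect_min_len SSR detection and perfection thresholds
#'   (nt).
#' @param min_aa Minimum ORF length in codons.
#' @param flank_len Flank length for primer design (nt).
#' @param primer_len,gc_range,max_homopolymer Primer constraints (see
#'   [suggest_primers()]).
#' @param max_product Maximum in-silico PCR product (nt).
#' @param anchor_k Seed length for cDNA anchoring.
#' @param max_markers Cap on the number of SSR-containing cDNAs carried into
#'   primer design and mapping.
#' @param k_groups Number of accession groups cut from the dendrogram.
#' @param alpha Adjusted-p significance threshold.
#' @param seed Integer seed for any stage that randomizes (none do by
#'   default; recorded in the manifest).
#' @return A list of class `run_config`.
#' @export
run_config <- function(fasta,
                       genome = NULL,
                       genotypes = NULL,
                       annotation = NULL,
                       selected = NULL,
                       universe = NULL,
                       n_screened = NULL,
                       min_len = 18,
                       perfect_min_len = 20,
                       min_aa = 30,
                       flank_len = 150,
                       primer_len = c(18L, 24L),
                       gc_range = c(40, 60),
                       max_homopolymer = 3L,
                       max_product = 2000,
                       anchor_k = 21,
                       max_markers = 38L,
                       k_groups = 2L,
                       alpha = 0.05,
                       seed = 1L) {
  stopifnot(min_len > 0, perfect_min_len > 0, flank_len > 0, max_product > 0,
            alpha > 0, alpha < 1)
  if (perfect_min_len < min_len) {
    warning("`perfect_min_len` is below `min_len`; every run will be perfect",
            call. = FALSE)
  }
  structure(as.list(environment()), class = "run_config")
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full SSR marker pipeline
#'
#' Executes mine -> summarize -> ORF context -> mapping/in-silico PCR ->
#' marker scoring/clustering -> enrichment, writing one TSV/BED file per
#' result plus a machine-readable manifest with an MD5 checksum per output.
#' Stages whose inputs are not configured are skipped; a rerun with the same
#' config and inputs is byte-identical. Any stage failure aborts with the
#' stage name.
#'
#' @param config A [run_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly: a list with `files` (named MD5 vector),
#'   `stages` run, and the scalar config values.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  note <- function(name) outputs <<- c(outputs, name)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv_plain(df, path)
    outputs <<- c(outputs, name)
  }

  seqs <- stage_try("mine", {
    if (!file.exists(config$fasta)) stop("cDNA FASTA not found: ", config$fasta)
    read_fasta(config$fasta)
  })
  ssrs <- stage_try("mine", find_ssrs(seqs, config$min_len, config$perfect_min_len))
  stage_try("mine", {
    write_ssrs(ssrs, file.path(out_dir, "ssrs.tsv"))
    note("ssrs.tsv")
  })

  stage_try("summarize", {
    n_screened <- config$n_screened %||% length(seqs)
    summ <- summarize_ssrs(ssrs, n_screened)
    emit(summ$type_table, "type_table.tsv")
    emit(summ$motif_table, "motif_table.tsv")
    emit(summ$repeat_bins, "repeat_bins.tsv")
    emit(summ$cdna_table, "cdna_table.tsv")
    emit(summ$incidence, "incidence.tsv")
    emit(summ$perfection_table, "perfection_table.tsv")
  })

  stage_try("orfctx", {
    ctx <- locate_ssr_in_gene(seqs, ssrs, min_aa = config$min_aa)
    emit(ctx, "ssr_context.tsv")
  })

  stages <- c("mine", "summarize", "orfctx")

  if (!is.null(config$genome)) {
    stage_try("mappcr", {
      if (!file.exists(config$genome)) {
        stop("genome FASTA not found: ", config$genome)
      }
      genome <- read_fasta(config$genome)
      res <- map_markers(seqs, ssrs, genome, config)
      emit(res$placements, "placements.tsv")
      emit(res$primers, "primers.tsv")
      emit(res$amplicons, "amplicons.tsv")
      write_physical_map(res$amplicons[res$amplicons$mapped, ],
                         file.path(out_dir, "physical_map.bed"))
      note("physical_map.bed")
    })
    stages <- c(stages, "mappcr")
  }

  if (!is.null(config$genotypes)) {
    stage_try("markers", {
      gm <- read_genotypes(config$genotypes)
      pol <- score_polymorphism(gm)
      emit(pol$markers, "polymorphism.tsv")
      emit(tibble::tibble(n_polymorphic = pol$n_polymorphic,
                          n_markers = pol$n_markers,
                          denominator = pol$denominator,
                          rate = pol$rate), "polymorphism_rate.tsv")
      bc <- bicluster(gm, k = config$k_groups)
      emit(tibble::tibble(accession = names(bc$groups),
                          group = unname(bc$groups)), "accession_groups.tsv")
      nwk <- export_newick(bc)
      writeLines(nwk, file.path(out_dir, "dendrograms.nwk"))
      note("dendrograms.nwk")
      emit(tibble::as_tibble(bc$matrix, rownames = "accession"),
           "heatmap_matrix.tsv")
    })
    stages <- c(stages, "markers")
  }

  if (!is.null(config$annotation) && !is.null(config$selected)) {
    stage_try("enrich", {
      ann <- tibble::as_tibble(utils::read.delim(config$annotation,
                                                 stringsAsFactors = FALSE))
      sel <- readLines(config$selected)
      sel <- sel[nzchar(sel)]
      uni <- NULL
      if (!is.null(config$universe)) {
        uni <- readLines(config$universe)
        uni <- uni[nzchar(uni)]
      }
      enr <- hypergeom_enrichment(sel, ann, universe = uni,
                                  alpha = config$alpha)
      emit(tibble::as_tibble(enr), "enrichment.tsv")
    })
    stages <- c(stages, "enrich")
  }

  files <- file.path(out_dir, outputs)
  manifest <- list(
    stages = stages,
    files = as.list(stats::setNames(unname(tools::md5sum(files)), outputs)),
    config = config_scalars(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

config_scalars <- function(config) {
  keep <- c("min_len", "perfect_min_len", "min_aa", "flank_len",
            "max_homopolymer", "max_product", "anchor_k", "max_markers",
            "k_groups", "alpha", "seed")
  config[keep]
}

# Flank extraction -> primer design -> anchoring -> in-silico PCR for up to
# `max_markers` SSR-containing cDNAs (first SSR per cDNA).
map_markers <- function(seqs, ssrs, genome, config) {
  first <- ssrs[!duplicated(ssrs$seq_id), ]
  first <- utils::head(first, config$max_markers)
  placements <- list(); primers <- list(); amplicons <- list()
  for (i in seq_len(nrow(first))) {
    rec <- first[i, ]
    marker <- sprintf("mk_%s", rec$seq_id)
    cdna <- seqs[[rec$seq_id]]
    pl <- anchor_cdna(genome, cdna, cdna_id = rec$seq_id, k = config$anchor_k)
    if (nrow(pl) > 0) placements[[length(placements) + 1]] <- pl
    fl <- extract_flanks(cdna, rec, flank_len = config$flank_len)
    pp <- suggest_primers(fl$left, fl$right, primer_len = config$primer_len,
                          gc_range = config$gc_range,
                          max_homopolymer = config$max_homopolymer)
    if (nrow(pp) == 0) next
    primers[[length(primers) + 1]] <- dplyr::bind_cols(
      tibble::tibble(marker = marker, seq_id = rec$seq_id), pp
    )
    hits <- match_probe_pair(genome, pp$fwd, pp$rev,
                             max_product = config$max_product)
    if (nrow(hits) > 0) {
      hits$marker <- marker
      hits$mapped <- TRUE
      amplicons[[length(amplicons) + 1]] <- hits
    }
  }
  empty_amp <- tibble::tibble(chrom = character(), start = integer(),
                              end = integer(), product_len = integer(),
                              orientation = character(), marker = character(),
                              mapped = logical())
  list(
    placements = if (length(placements)) dplyr::bind_rows(placements) else
      tibble::tibble(cdna_id = character(), chrom = character(),
                     start = integer(), end = integer(), strand = character(),
                     matched_fraction = double()),
    primers = if (length(primers)) dplyr::bind_rows(primers) else
      dplyr::bind_cols(tibble::tibble(marker = character(),
                                      seq_id = character()),
                       empty_primer_pair()),
    amplicons = if (length(amplicons)) dplyr::bind_rows(amplicons) else empty_amp
  )
}

#' One-command synthetic end-to-end demonstration
#'
#' Generates a synthetic cDNA corpus with planted SSRs, a genome embedding
#' it, a genotype table for two accession groups and an annotation with one
#' planted term, writes them under `out_dir/inputs/`, and runs the full
#' pipeline on them. Every input has known truth, so the run's outputs can be
#' checked exactly.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed controlling all synthetic inputs.
#' @param n_sequences Corpus size.
#' @return A list with `manifest` (from [run_all()]), `truth` (planted SSRs,
#'   genome placements, genotype truth, planted term) and `paths`.
#' @export
run_demo <- function(out_dir, seed = 1, n_sequences = 120) {
  dir.create(file.path(out_dir, "inputs"), showWarnings = FALSE,
             recursive = TRUE)
  cfg <- synth_config(n_sequences = n_sequences,
                      length_range = c(300L, 900L),
                      ssr_density = 0.8, seed = seed)
  corpus <- gen_cdna_corpus(cfg)
  gen <- gen_genome(corpus$sequences, flank_len = 300L, n_chromosomes = 3L,
                    seed = seed + 1L)
  gt <- gen_genotypes(n_markers = 35, n_group1 = 9, n_group2 = 2,
                      divergence = 22 / 35, seed = seed + 2L)
  ann <- gen_annotation(n_genes = 1000, n_terms = 50, enriched_term_size = 40,
                        selected_size = 60, selected_overlap = 25,
                        seed = seed + 3L)
  paths <- list(
    fasta = file.path(out_dir, "inputs", "cdna.fa"),
    genome = file.path(out_dir, "inputs", "genome.fa"),
    genotypes = file.path(out_dir, "inputs", "genotypes.csv"),
    annotation = file.path(out_dir, "inputs", "annotation.tsv"),
    selected = file.path(out_dir, "inputs", "selected.txt"),
    universe = file.path(out_dir, "inputs", "universe.txt")
  )
  write_fasta(corpus$sequences, paths$fasta)
  write_fasta(gen$genome, paths$genome)
  utils::write.csv(gt$genotypes, paths$genotypes, row.names = FALSE,
                   quote = FALSE)
  write_tsv_plain(ann$annotation, paths$annotation)
  writeLines(ann$selected, paths$selected)
  writeLines(ann$universe, paths$universe)
  config <- run_config(
    fasta = paths$fasta, genome = paths$genome,
    genotypes = paths$genotypes, annotation = paths$annotation,
    selected = paths$selected, universe = paths$universe, seed = seed
  )
  manifest <- run_all(config, file.path(out_dir, "results"))
  list(
    manifest = manifest,
    truth = list(ssrs = corpus$truth, placements = gen$placements,
                 genotypes = gt$truth, planted_term = ann$planted_term),
    paths = paths,
    config = config
  )
}
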
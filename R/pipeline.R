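#' Configure an end-to-end pipeline run
#'
#' @param scenario A [clip_scenario()].
#' @param outdir Output directory for stage artifacts (created if
#'   needed); `NULL` keeps everything in memory.
#' @param stages Character subset of
#'   `c("footprints", "consensus", "repro", "compare", "quant")`;
#'   simulation always runs since later stages consume it.
#' @param min_support,min_overlap Consensus thresholds (see
#'   [consensus_footprints()]).
#' @param idr_threshold Global IDR cutoff for reproducibility counts.
#' @param seed Root seed; overrides the scenario's seed so one
#'   configuration object fully determines the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = clip_scenario(),
                            outdir = NULL,
                            stages = c("footprints", "consensus", "repro",
                                       "compare", "quant"),
                            min_support = 2, min_overlap = 2,
                            idr_threshold = 0.05,
                            seed = scenario$seed) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (min_support < 1 || min_overlap < 1)
    abort("min_support and min_overlap must be >= 1")
  if (idr_threshold <= 0 || idr_threshold > 1)
    abort("idr_threshold must be in (0, 1]")
  structure(list(scenario = scenario, outdir = outdir, stages = stages,
                 min_support = min_support, min_overlap = min_overlap,
                 idr_threshold = idr_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full synthetic CLIP-seq analysis pipeline
#'
#' Executes the stages in order — simulate (annotation, true sites,
#' per-condition replicates, background), footprints (background
#' depletion then merging per replicate), consensus (majority-consensus
#' footprints and bound-gene sets per condition), repro (pairwise IDR
#' reproducibility within each condition), compare (bound-gene partition,
#' naive-vs-severe footprint delta, motif enrichment in naive footprint
#' sequences) and quant (PSI/delta-PSI, fold changes, inclusion ratios
#' and the exact rank test on the simulated assay tables) — logging
#' interval counts in and out of every filtering step.  With an `outdir`,
#' per-stage artifacts are written (BED6, TSV, JSON) and the manifest
#' records their MD5 hashes; identical configuration and seed give
#' identical artifact hashes.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_manifest` list: `summary` (per-condition tibble of
#'   counts), `results` (stage outputs), `log` (per-stage count tibble),
#'   `files` (tibble of written artifacts and MD5 hashes), `seed`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  sc <- config$scenario
  sc$seed <- config$seed
  outdir <- config$outdir
  if (!is.null(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_rows <- list()
  note <- function(stage, what, n) {
    log_rows[[length(log_rows) + 1]] <<- tibble(stage = stage, what = what,
                                                n = as.integer(n))
  }
  results <- list()

  # --- simulate ---------------------------------------------------------
  annotation <- make_toy_annotation(sc)
  true_sites <- simulate_true_sites(annotation, sc)
  background <- simulate_background(annotation, sc)
  note("simulate", "true_sites", nrow(true_sites))
  note("simulate", "background_intervals", nrow(background))
  conditions <- names(sc$condition_loss)
  replicates <- lapply(setNames(conditions, conditions), function(cond) {
    simulate_replicate_peaks(true_sites, sc,
                             n_reps = sc$n_reps_by_condition[[cond]],
                             condition = cond)
  })
  for (cond in conditions)
    note("simulate", paste0("peaks_", cond),
         sum(vapply(replicates[[cond]], nrow, 0L)))
  results$annotation <- annotation
  results$true_sites <- true_sites
  results$background <- background

  # --- footprints: deplete background, then merge -----------------------
  footprints <- replicates
  if ("footprints" %in% config$stages) {
    footprints <- lapply(replicates, function(reps) lapply(reps, function(r) {
      depleted <- interval_subtract(r, background)
      merged <- interval_merge(depleted)
      # carry best score/support of the contributing peaks onto merged
      # footprints so downstream IDR stays scored
      hits <- GenomicRanges::findOverlaps(intervals_to_granges(merged),
                                          intervals_to_granges(depleted),
                                          ignore.strand = TRUE)
      qh <- S4Vectors::queryHits(hits)
      merged$score <- as.numeric(tapply(depleted$score[S4Vectors::subjectHits(hits)],
                                        qh, max)[as.character(seq_len(nrow(merged)))])
      merged$support <- as.integer(tapply(depleted$support[S4Vectors::subjectHits(hits)],
                                          qh, sum)[as.character(seq_len(nrow(merged)))])
      merged
    }))
    for (cond in conditions) {
      note("footprints", paste0("before_depletion_", cond),
           sum(vapply(replicates[[cond]], nrow, 0L)))
      note("footprints", paste0("after_merge_", cond),
           sum(vapply(footprints[[cond]], nrow, 0L)))
    }
    results$footprints <- footprints
  }

  # --- consensus --------------------------------------------------------
  if ("consensus" %in% config$stages) {
    consensus <- lapply(setNames(conditions, conditions), function(cond)
      consensus_footprints(footprints[[cond]],
                           min_support = config$min_support,
                           min_overlap = config$min_overlap,
                           annotation = annotation))
    results$consensus <- consensus
    results$bound_genes <- lapply(consensus, bound_gene_set)
    for (cond in conditions) {
      note("consensus", paste0("footprints_", cond),
           nrow(consensus[[cond]]))
      note("consensus", paste0("bound_genes_", cond),
           length(results$bound_genes[[cond]]))
    }
  }

  # --- repro ------------------------------------------------------------
  if ("repro" %in% config$stages) {
    repro <- lapply(setNames(conditions, conditions), function(cond) {
      grp <- footprints[[cond]]
      names(grp) <- paste0(cond, "_rep", seq_along(grp))
      pairwise_group_reproducibility(
        grp, seed = derive_seed(config$seed, paste0("repro_", cond)),
        idr_threshold = config$idr_threshold,
        min_overlap = config$min_overlap)
    })
    results$repro <- repro
    for (cond in conditions)
      note("repro", paste0("acceptable_pairs_", cond),
           sum(repro[[cond]]$acceptable, na.rm = TRUE))
  }

  # --- compare ----------------------------------------------------------
  if ("compare" %in% config$stages && "consensus" %in% config$stages) {
    results$venn <- venn_partition(results$bound_genes)
    ref <- conditions[1]
    last <- conditions[length(conditions)]
    results$delta <- footprint_delta(results$consensus[[ref]],
                                     results$consensus[[last]])
    # depletion can leave fragments shorter than the motif; those carry
    # no sequence signal worth scanning
    wide <- filter(results$consensus[[ref]],
                   .data$end - .data$start >= max(10, nchar(sc$motif)))
    seqs <- simulate_sequences(wide, sc)
    results$motif <- kmer_enrichment(
      seqs, sc$motif, seed = derive_seed(config$seed, "motif"))
    note("compare", "union_bound_genes", attr(results$venn, "union_size"))
    note("compare", "delta_lost_bp",
         sum(results$delta$lost$end - results$delta$lost$start))
  }

  # --- quant ------------------------------------------------------------
  if ("quant" %in% config$stages) {
    tables <- simulate_assay_tables(sc)
    groups <- names(sc$psi_by_group)
    results$assays <- list(
      tables = tables,
      delta_psi = delta_psi(tables$junctions, control = groups[1],
                            case = groups[2]),
      fold_change = ddct_fold_change(tables$ct, calibrator = groups[1]),
      inclusion = mutate(tables$bands,
                         inclusion = inclusion_ratio(.data$band_a,
                                                     .data$band_b)))
    fc <- results$assays$fold_change
    results$assays$rank_test <- group_test(
      fc$fold_change[fc$group == groups[1]],
      fc$fold_change[fc$group == groups[2]],
      test = "mann_whitney_exact")
    note("quant", "assay_samples", nrow(tables$junctions))
  }

  # --- artifacts and manifest ------------------------------------------
  files <- tibble(path = character(), md5 = character())
  if (!is.null(outdir)) {
    emit <- function(obj, fname, writer) {
      p <- file.path(outdir, fname)
      writer(obj, p)
      files <<- bind_rows(files, tibble(path = fname,
                                        md5 = unname(tools::md5sum(p))))
    }
    emit(annotation, "annotation.tsv", write_gene_models)
    emit(true_sites, "true_sites.bed", write_bed)
    emit(background, "background.bed", write_bed)
    if (!is.null(results$consensus))
      for (cond in conditions)
        emit(select(results$consensus[[cond]], -dplyr::any_of("genes")),
             paste0("consensus_", cond, ".bed"), write_bed)
    if (!is.null(results$repro))
      emit(bind_rows(results$repro), "repro.tsv",
           function(x, p) readr::write_tsv(x, p))
    if (!is.null(results$venn))
      emit(results$venn, "venn.json", function(x, p)
        jsonlite::write_json(select(as_tibble(x), -"conditions"), p,
                             auto_unbox = TRUE, digits = NA))
    if (!is.null(results$assays))
      emit(results$assays$fold_change, "fold_change.tsv",
           function(x, p) readr::write_tsv(x, p))
  }

  summary <- tibble(condition = conditions,
                    n_replicates = unname(sc$n_reps_by_condition[conditions]),
                    condition_loss = unname(sc$condition_loss[conditions]),
                    n_consensus = vapply(conditions, function(cond)
                      if (is.null(results$consensus)) NA_integer_
                      else nrow(results$consensus[[cond]]), 0L),
                    n_bound_genes = vapply(conditions, function(cond)
                      if (is.null(results$bound_genes)) NA_integer_
                      else length(results$bound_genes[[cond]]), 0L))
  if (!is.null(results$venn)) {
    uniq <- results$venn %>%
      filter(lengths(.data$conditions) == 1) %>%
      mutate(condition = map_chr(.data$conditions, 1))
    summary <- left_join(summary,
                         select(as_tibble(uniq), "condition",
                                n_unique_genes = "n"),
                         by = "condition")
  }
  structure(list(summary = summary, results = results,
                 log = bind_rows(log_rows), files = files,
                 seed = config$seed),
            class = "pipeline_manifest")
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("<pipeline_manifest> seed ", x$seed, "\n", sep = "")
  print(x$summary)
  invisible(x)
}
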
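sc_small <- clip_scenario(seed = 42, n_chroms = 2, chrom_length = 100000L,
                          n_genes = 10, n_true_sites = 40,
                          n_noise_peaks_per_rep = 20)

test_that("toy annotation is deterministic, non-overlapping and accounts for every base", {
  ann1 <- make_toy_annotation(sc_small)
  ann2 <- make_toy_annotation(sc_small)
  expect_identical(as.data.frame(ann1), as.data.frame(ann2))

  feats <- dplyr::filter(ann1, feature != "gene")
  # per-base bookkeeping: annotated feature bases + intergenic bases
  # must tile the genome exactly, i.e. features never overlap
  total <- 0
  for (cm in names(chrom_lengths(ann1))) {
    m <- logical(chrom_lengths(ann1)[[cm]])
    f <- feats[feats$chrom == cm, ]
    for (i in seq_len(nrow(f))) {
      expect_false(any(m[(f$start[i] + 1):f$end[i]]))  # no overlap
      m[(f$start[i] + 1):f$end[i]] <- TRUE
    }
    total <- total + sum(m)
  }
  expect_equal(total, sum(feats$end - feats$start))
  expect_lt(total, sum(chrom_lengths(ann1)))  # intergenic space present
  # each gene: one 5'UTR, one 3'UTR, >= 2 CDS exons
  per_gene <- dplyr::count(feats, gene_id, feature)
  expect_true(all(per_gene$n[per_gene$feature == "five_utr"] == 1))
  expect_true(all(per_gene$n[per_gene$feature == "three_utr"] == 1))
  expect_true(all(per_gene$n[per_gene$feature == "cds"] >= 2))
})

test_that("empty annotation and capacity errors behave as specified", {
  ann0 <- make_toy_annotation(clip_scenario(seed = 1, n_genes = 0))
  expect_s3_class(ann0, "clip_annotation")
  expect_identical(nrow(ann0), 0L)
  expect_error(
    make_toy_annotation(clip_scenario(seed = 1, n_chroms = 1,
                                      chrom_length = 5000L, n_genes = 50)),
    "cannot place")
})

test_that("true sites land in their sampled region class and are deterministic", {
  ann <- make_toy_annotation(sc_small)
  sc_intron <- clip_scenario(seed = 7, n_chroms = 2, chrom_length = 100000L,
                             n_genes = 10, n_true_sites = 60,
                             region_bias = c(intron = 1))
  sites <- simulate_true_sites(ann, sc_intron)
  assigned <- genic_region_assign(sites, ann)
  expect_true(all(assigned$region == "intron"))
  props <- genic_region_proportions(sites, ann)
  expect_equal(props$proportion[props$region == "intron"], 1)

  expect_identical(simulate_true_sites(ann, sc_small),
                   simulate_true_sites(ann, sc_small))
  none <- simulate_true_sites(ann, clip_scenario(seed = 1, n_true_sites = 0))
  expect_identical(nrow(none), 0L)
})

test_that("matched replicate scores carry the planted correlation", {
  sc <- clip_scenario(seed = 3, n_chroms = 4, chrom_length = 2000000L,
                      n_genes = 300, n_true_sites = 5000,
                      pi1 = 0.999, rho1 = 0.999,
                      n_noise_peaks_per_rep = 0)
  ann <- make_toy_annotation(sc)
  sites <- simulate_true_sites(ann, sc)
  reps <- simulate_replicate_peaks(sites, sc, n_reps = 2)
  merged <- dplyr::inner_join(reps[[1]], reps[[2]], by = "name")
  expect_gt(nrow(merged), 4500)
  expect_gt(cor(merged$score.x, merged$score.y, method = "spearman"), 0.9)
})

test_that("full condition loss leaves only noise peaks", {
  ann <- make_toy_annotation(sc_small)
  sites <- simulate_true_sites(ann, sc_small)
  sc_loss <- clip_scenario(seed = 9, n_chroms = 2, chrom_length = 100000L,
                           n_genes = 10, n_true_sites = 40,
                           n_noise_peaks_per_rep = 20,
                           condition_loss = c(severe = 1),
                           n_reps_by_condition = c(severe = 2L))
  reps <- simulate_replicate_peaks(sites, sc_loss, n_reps = 2,
                                   condition = "severe")
  for (r in reps) {
    expect_identical(nrow(r), 20L)
    expect_true(all(startsWith(r$name, "noise")))
  }
})

test_that("background counts follow the Poisson rate and are deterministic", {
  ann <- make_toy_annotation(sc_small)
  rate <- 0.5
  sc_bg <- clip_scenario(seed = 1, n_chroms = 2, chrom_length = 100000L,
                         n_genes = 10, background_rate = rate)
  counts <- vapply(1:100, function(s)
    nrow(simulate_background(ann, sc_bg, seed = s)), 0L)
  lambda <- rate * sum(chrom_lengths(ann)) / 1000
  se <- sqrt(lambda / 100)
  expect_lt(abs(mean(counts) - lambda), 3 * se)

  expect_identical(simulate_background(ann, sc_bg),
                   simulate_background(ann, sc_bg))
  sc0 <- clip_scenario(seed = 1, background_rate = 0)
  expect_identical(nrow(simulate_background(ann, sc0)), 0L)
})

test_that("sequence simulation plants the motif at the requested rate", {
  fps <- tibble::tibble(chrom = "chr1", start = seq(0, 990, by = 10) * 100,
                        end = seq(0, 990, by = 10) * 100 + 50)
  sc1 <- clip_scenario(seed = 5, motif = "UAG", motif_enrichment = 1)
  seqs <- simulate_sequences(fps, sc1)
  expect_identical(nrow(seqs), nrow(fps))
  expect_true(all(nchar(seqs$seq) == 50))
  expect_identical(simulate_sequences(fps, sc1), seqs)
  enr <- kmer_enrichment(seqs, "UAG", n_shuffles = 50, seed = 2)
  expect_lt(abs(enr$z), 4)

  sc5 <- clip_scenario(seed = 5, motif = "UAG", motif_enrichment = 5)
  enr5 <- kmer_enrichment(simulate_sequences(fps, sc5), "UAG",
                          n_shuffles = 50, seed = 2)
  expect_gt(enr5$z, 5)

  tiny <- tibble::tibble(chrom = "chr1", start = 0, end = 2)
  expect_error(simulate_sequences(tiny, sc1), "motif longer")
})

test_that("assay tables recover the planted PSI at depth and reject zero depth", {
  sc <- clip_scenario(seed = 8, junction_depth = 10000L,
                      psi_by_group = c(control = 0.5, case = 0.5))
  tables <- simulate_assay_tables(sc)
  q <- psi(tables$junctions)
  expect_true(all(abs(q$psi - 0.5) < 0.02))
  expect_identical(simulate_assay_tables(sc)$ct, tables$ct)
  expect_error(clip_scenario(junction_depth = 0), "junction_depth")
})
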
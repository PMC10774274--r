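test_that("subtract matches its definition on fixtures", {
  a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  b <- tibble::tibble(chrom = "chr1", start = 40, end = 60)
  out <- interval_subtract(a, b)
  expect_equal(out$start, c(0, 60))
  expect_equal(out$end, c(40, 100))
  # empty background is the identity
  expect_identical(interval_subtract(a, b[0, ]), as_interval_tbl(a))
  # whole coverage removes the interval
  expect_identical(nrow(interval_subtract(b, a)), 0L)
  # metadata follows the fragments
  a$name <- "site1"
  expect_equal(interval_subtract(a, b)$name, c("site1", "site1"))
})

test_that("merge combines overlapping and book-ended intervals only", {
  book <- tibble::tibble(chrom = "chr1", start = c(0, 10), end = c(10, 20))
  expect_equal(interval_merge(book),
               tibble::tibble(chrom = "chr1", start = 0L, end = 20L))
  apart <- tibble::tibble(chrom = "chr1", start = c(0, 20), end = c(10, 30))
  expect_equal(nrow(interval_merge(apart)), 2L)
  expect_equal(nrow(interval_merge(apart, gap = 10)), 1L)
})

test_that("subtract and merge agree with the per-base mask oracle", {
  chrom_len <- 10000
  withr::with_seed(101, {
    for (case in 1:60) {
      a <- random_intervals(sample(1:25, 1), chrom_len)
      b <- random_intervals(sample(0:25, 1), chrom_len)
      got_sub <- interval_subtract(a, b)[, c("chrom", "start", "end")]
      want_sub <- if (nrow(b)) oracle_subtract(a, b, chrom_len) else
        dplyr::arrange(a, chrom, start, end)
      expect_equal(as.data.frame(got_sub), as.data.frame(want_sub))
      got_merge <- interval_merge(a)
      expect_equal(as.data.frame(got_merge),
                   as.data.frame(oracle_merge(a, chrom_len)))
    }
  })
})

test_that("merge is idempotent and subtract obeys its algebra", {
  withr::with_seed(7, {
    a <- random_intervals(30, 10000)
    m <- interval_merge(a)
    expect_identical(interval_merge(m), m)
    expect_identical(nrow(interval_subtract(a, a)), 0L)
  })
})

test_that("consensus support respects the strict >1 nt overlap rule", {
  # candidate seeded by rep1; rep2 overlaps by exactly 1 nt -> no support
  rep1 <- tibble::tibble(chrom = "chr1", start = 100, end = 150)
  rep2_1nt <- tibble::tibble(chrom = "chr1", start = 149, end = 200)
  rep3 <- tibble::tibble(chrom = "chr1", start = 500, end = 550)
  none <- consensus_footprints(list(rep1, rep2_1nt, rep3))
  expect_identical(nrow(none), 0L)
  # 2 nt overlap does confer support
  rep2_2nt <- tibble::tibble(chrom = "chr1", start = 148, end = 200)
  kept <- consensus_footprints(list(rep1, rep2_2nt, rep3))
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$support, 2L)
  expect_identical(kept$n_replicates, 3L)
  # the retained region is the merged union of the contributing peaks
  expect_equal(c(kept$start, kept$end), c(100L, 200L))
})

test_that("2-of-3 and 2-of-4 majority retention matches the printed rule", {
  fp <- function(s, e) tibble::tibble(chrom = "chr1", start = s, end = e)
  shared <- fp(100, 150)
  # present in 2 of 3 with 5 nt mutual overlap -> retained, support 2
  reps3 <- list(shared, fp(145, 190), fp(800, 850))
  out3 <- consensus_footprints(reps3)
  expect_identical(out3$support, 2L)
  # present in 2 of 4 -> retained under the same min_support = 2
  reps4 <- list(shared, fp(145, 190), fp(800, 850), fp(900, 950))
  out4 <- consensus_footprints(reps4)
  expect_identical(out4$support, 2L)
  expect_identical(out4$n_replicates, 4L)
  # identical replicates: everything retained at full support
  same <- list(shared, shared, shared, shared)
  expect_identical(consensus_footprints(same)$support, 4L)
})

test_that("consensus agrees with the oracle, is order-invariant and monotone", {
  chrom_len <- 10000
  withr::with_seed(23, {
    for (case in 1:25) {
      reps <- lapply(1:3, function(i) random_intervals(sample(3:12, 1),
                                                       chrom_len))
      got <- consensus_footprints(reps)
      want <- oracle_consensus(reps, chrom_len)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$support, want$support)
      perm <- consensus_footprints(rev(reps))
      expect_equal(as.data.frame(got), as.data.frame(perm))
      # raising either threshold never yields more footprints
      expect_lte(nrow(consensus_footprints(reps, min_support = 3)),
                 nrow(got))
      expect_lte(nrow(consensus_footprints(reps, min_overlap = 10)),
                 nrow(got))
    }
  })
})

test_that("closest feature assigns overlaps, ties and missing chromosomes", {
  ann <- make_toy_annotation(clip_scenario(seed = 2, n_chroms = 1,
                                           chrom_length = 100000L,
                                           n_genes = 6))
  genes <- dplyr::filter(ann, feature == "gene")
  inside <- tibble::tibble(chrom = genes$chrom[1],
                           start = genes$start[1] + 10,
                           end = genes$start[1] + 40)
  hit <- closest_feature(inside, ann)
  expect_identical(hit$gene, genes$gene_id[1])
  expect_identical(hit$distance, 0L)

  # constructed tie: equidistant between two genes, both reported, in
  # lexicographic order
  tie_ann <- tibble::tibble(
    gene_id = c("geneB", "geneA"), chrom = "chr1", strand = "+",
    feature = "gene", start = c(0, 1200), end = c(500, 1500))
  attr(tie_ann, "chrom_lengths") <- c(chr1 = 10000L)
  class(tie_ann) <- c("clip_annotation", class(tie_ann))
  mid <- tibble::tibble(chrom = "chr1", start = 600, end = 1100)
  tie <- closest_feature(mid, tie_ann)
  expect_identical(tie$genes[[1]], c("geneA", "geneB"))
  expect_identical(tie$gene, "geneA")
  expect_identical(tie$distance, 100L)

  off <- closest_feature(tibble::tibble(chrom = "chrZ", start = 0, end = 10),
                         ann)
  expect_true(is.na(off$gene))
  expect_true(is.na(off$distance))
})

test_that("closest feature equals the exhaustive all-pairs scan", {
  ann <- make_toy_annotation(clip_scenario(seed = 6, n_chroms = 2,
                                           chrom_length = 100000L,
                                           n_genes = 12))
  genes <- dplyr::filter(ann, feature == "gene")
  withr::with_seed(15, {
    q <- dplyr::bind_rows(random_intervals(40, 100000, "chr1"),
                          random_intervals(40, 100000, "chr2"))
    got <- closest_feature(q, ann)
    want <- oracle_closest(q, genes)
    for (i in seq_len(nrow(q))) {
      expect_identical(got$genes[[i]], want[[i]]$genes)
      expect_identical(got$distance[i],
                       as.integer(want[[i]]$distance))
    }
  })
})

test_that("region assignment uses majority bases with CDS precedence on ties", {
  ann <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = "+",
    feature = c("gene", "cds", "intron"),
    start = c(0, 0, 100), end = c(1000, 100, 1000))
  attr(ann, "chrom_lengths") <- c(chr1 = 10000L)
  class(ann) <- c("clip_annotation", class(ann))
  # 30 nt in CDS, 10 nt in intron -> CDS by majority
  x <- tibble::tibble(chrom = "chr1", start = 70, end = 110)
  expect_identical(as.character(genic_region_assign(x, ann)$region), "cds")
  # exact 20/20 tie -> CDS by precedence
  tie <- tibble::tibble(chrom = "chr1", start = 80, end = 120)
  expect_identical(as.character(genic_region_assign(tie, ann)$region), "cds")
  # intergenic-only input: zero denominator flagged
  out <- genic_region_proportions(
    tibble::tibble(chrom = "chr1", start = 5000, end = 5050), ann)
  expect_true(attr(out, "zero_denominator"))
  expect_identical(attr(out, "n_intergenic"), 1L)
})

test_that("region proportions recover the generative region bias", {
  bias <- c(intron = 0.6, cds = 0.2, five_utr = 0.1, three_utr = 0.1)
  sc <- clip_scenario(seed = 12, n_chroms = 2, chrom_length = 800000L,
                      n_genes = 150, n_true_sites = 2000,
                      region_bias = bias)
  ann <- make_toy_annotation(sc)
  sites <- simulate_true_sites(ann, sc)
  props <- genic_region_proportions(sites, ann)
  got <- setNames(props$proportion, as.character(props$region))
  for (cls in names(bias))
    expect_lt(abs(got[[cls]] - bias[[cls]]), 0.03)
})
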
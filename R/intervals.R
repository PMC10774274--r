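#' Genomic interval tables
#'
#' Throughout the package genomic intervals are plain tibbles in BED
#' convention: 0-based, half-open `[start, end)` coordinates with columns
#' `chrom`, `start`, `end` and optionally `strand`, `name`, `score`,
#' `support`.  `as_interval_tbl()` validates and normalises such a table.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @return A sorted tibble of intervals.
#' @examples
#' as_interval_tbl(data.frame(chrom = "chr1", start = 0, end = 100))
#' @export
as_interval_tbl <- function(x) {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    abort(paste0("missing interval columns: ",
                 paste(missing_cols, collapse = ", ")))
  if (nrow(x)) {
    if (any(!nzchar(as.character(x$chrom)))) abort("chrom must be non-empty")
    if (any(x$start < 0) || any(x$start >= x$end))
      abort("intervals need 0 <= start < end")
  }
  arrange(x, .data$chrom, .data$start, .data$end)
}

# validate without sorting, for per-row operations that must preserve the
# caller's row order
validate_intervals <- function(x) {
  x <- as_tibble(x)
  miss <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(miss))
    abort(paste0("missing interval columns: ", paste(miss, collapse = ", ")))
  if (nrow(x) && (any(x$start < 0) || any(x$start >= x$end)))
    abort("intervals need 0 <= start < end")
  x
}

# tibble (0-based half-open) -> GRanges (1-based closed)
intervals_to_granges <- function(x, keep_strand = FALSE) {
  strand <- if (keep_strand && "strand" %in% names(x)) {
    s <- as.character(x$strand)
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand)
}

granges_to_intervals <- function(gr) {
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

#' Subtract background intervals from a set of sites
#'
#' Removes, base by base, every part of `a` covered by `b` — the background
#' depletion step of footprint construction, where sites recovered in the
#' size-matched input or pooled IgG control are treated as background
#' signal.  An interval of `a` wholly covered by `b` vanishes; an interval
#' split by `b` yields multiple fragments.  Metadata columns of `a` are
#' propagated to the fragments they came from.
#'
#' @param a,b Interval tibbles (see [as_interval_tbl()]).
#' @param ignore_strand Compare coordinates only (default), as with the
#'   default settings of the interval tools this mirrors.
#' @return Sorted interval tibble of the uncovered sub-segments of `a`.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "chr1", start = 40, end = 60)
#' interval_subtract(a, b)
#' @export
interval_subtract <- function(a, b, ignore_strand = TRUE) {
  a <- as_interval_tbl(a)
  b <- as_interval_tbl(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  gr_a <- intervals_to_granges(a, keep_strand = !ignore_strand)
  gr_b <- intervals_to_granges(b, keep_strand = !ignore_strand)
  frag_list <- GenomicRanges::subtract(gr_a, gr_b,
                                       ignore.strand = ignore_strand)
  n_frag <- S4Vectors::elementNROWS(frag_list)
  frags <- unlist(frag_list, use.names = FALSE)
  out <- granges_to_intervals(frags)
  meta <- a[rep(seq_len(nrow(a)), n_frag),
            setdiff(names(a), c("chrom", "start", "end")), drop = FALSE]
  out <- dplyr::bind_cols(out, meta)
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' Merge overlapping and book-ended intervals
#'
#' Combines intervals that overlap or touch end-to-start (book-ended) into
#' their union, yielding the minimal interval set covering the same bases —
#' the footprint-merging step applied to each immunoprecipitation sample.
#'
#' @inheritParams interval_subtract
#' @param gap Maximum separation (nt) still merged; `0` merges overlapping
#'   and book-ended intervals only.
#' @return Sorted tibble with columns `chrom`, `start`, `end`.
#' @examples
#' interval_merge(tibble::tibble(chrom = "chr1",
#'                               start = c(0, 10), end = c(10, 20)))
#' @export
interval_merge <- function(a, gap = 0, ignore_strand = TRUE) {
  if (gap < 0) abort("gap must be >= 0")
  a <- as_interval_tbl(a)
  if (nrow(a) == 0) return(tibble(chrom = character(), start = integer(),
                                  end = integer()))
  gr <- intervals_to_granges(a, keep_strand = !ignore_strand)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1L,
                                  ignore.strand = ignore_strand)
  arrange(granges_to_intervals(merged), .data$chrom, .data$start, .data$end)
}

#' Majority-consensus footprints across replicates
#'
#' Builds candidate regions by merging the union of all replicate
#' footprints, then scores each candidate by cross-sample consistency:
#' two replicates agree on a candidate when a footprint of one overlaps a
#' footprint of the other by at least `min_overlap` nt, and a candidate's
#' support is the largest agreement neighbourhood — one seed replicate
#' plus every replicate agreeing with it (a lone footprint has support
#' 1).  Candidates with support of at least `min_support` are retained:
#' the "2 of 3 or 2 of 4 samples with more than 1 nt overlap" rule, read
#' strictly so that a 1-nt overlap between samples does not confer
#' support (default `min_overlap = 2`).
#'
#' @param replicates List of interval tibbles, one per replicate, already
#'   background-depleted and merged.
#' @param min_support Minimum number of supporting replicates (default 2,
#'   the printed majority rule for groups of 3 or 4).
#' @param min_overlap Minimum overlap (nt) for a replicate to support a
#'   candidate; default 2 (the strict reading of "more than 1 nt").
#' @param annotation Optional gene annotation (see [make_toy_annotation()]);
#'   when given, each footprint carries its closest-gene assignment.
#' @return Tibble of class `consensus_footprints` with columns `chrom`,
#'   `start`, `end`, `support`, `n_replicates` and, with an annotation,
#'   `gene` (first closest gene) and `genes` (list column of all tied
#'   closest genes).
#' @examples
#' reps <- list(tibble::tibble(chrom = "chr1", start = 0, end = 50),
#'              tibble::tibble(chrom = "chr1", start = 10, end = 60),
#'              tibble::tibble(chrom = "chr1", start = 200, end = 240))
#' consensus_footprints(reps)
#' @export
consensus_footprints <- function(replicates, min_support = 2,
                                 min_overlap = 2, annotation = NULL) {
  if (!is.list(replicates) || length(replicates) < min_support)
    abort("need at least `min_support` replicate interval sets")
  if (min_overlap < 1) abort("min_overlap must be >= 1")
  replicates <- lapply(replicates, as_interval_tbl)
  n_rep <- length(replicates)
  pooled <- bind_rows(lapply(replicates, function(r)
    r[, c("chrom", "start", "end")]))
  cand <- interval_merge(pooled)
  if (nrow(cand) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  support = integer(), n_replicates = integer())
    class(out) <- c("consensus_footprints", class(out))
    return(out)
  }
  cand_gr <- intervals_to_granges(cand)
  rep_grs <- lapply(replicates, intervals_to_granges)
  # every replicate footprint lies inside exactly one candidate, because
  # candidates are the maximal merged components of the union
  present <- matrix(FALSE, nrow(cand), n_rep)
  for (r in seq_len(n_rep)) {
    if (nrow(replicates[[r]]) == 0) next
    hits <- GenomicRanges::findOverlaps(cand_gr, rep_grs[[r]],
                                        ignore.strand = TRUE)
    present[unique(S4Vectors::queryHits(hits)), r] <- TRUE
  }
  # agreement between replicate pairs within a candidate: some footprint
  # of one overlaps some footprint of the other by >= min_overlap nt
  agree <- array(FALSE, dim = c(nrow(cand), n_rep, n_rep))
  for (r in seq_len(n_rep - 1)) {
    if (nrow(replicates[[r]]) == 0) next
    cand_of_r <- rep(NA_integer_, nrow(replicates[[r]]))
    h <- GenomicRanges::findOverlaps(rep_grs[[r]], cand_gr,
                                     ignore.strand = TRUE)
    cand_of_r[S4Vectors::queryHits(h)] <- S4Vectors::subjectHits(h)
    for (s in (r + 1):n_rep) {
      if (nrow(replicates[[s]]) == 0) next
      hits <- GenomicRanges::findOverlaps(
        rep_grs[[r]], rep_grs[[s]],
        minoverlap = as.integer(min_overlap), ignore.strand = TRUE)
      ci <- unique(cand_of_r[S4Vectors::queryHits(hits)])
      ci <- ci[!is.na(ci)]
      agree[ci, r, s] <- TRUE
      agree[ci, s, r] <- TRUE
    }
  }
  support <- vapply(seq_len(nrow(cand)), function(ci) {
    per_seed <- vapply(seq_len(n_rep), function(r)
      if (present[ci, r]) 1L + sum(agree[ci, r, ]) else 0L, 0L)
    max(per_seed)
  }, 0L)
  out <- mutate(cand, support = support, n_replicates = n_rep)
  out <- filter(out, .data$support >= min_support)
  if (!is.null(annotation) && nrow(out)) {
    cf <- closest_feature(out, annotation)
    out$gene <- cf$gene
    out$genes <- cf$genes
    out$gene_distance <- cf$distance
  }
  class(out) <- c("consensus_footprints", class(out))
  out
}

#' Closest gene for each interval
#'
#' Assigns each interval the gene(s) at minimal genomic distance on its
#' chromosome (0 when overlapping; otherwise the number of bases between
#' the closest span edges).  Exact ties return all tied genes, ordered
#' lexicographically.  Intervals on chromosomes absent from the annotation
#' are flagged unassigned (`NA` gene, `NA` distance) rather than erroring.
#'
#' @param intervals Interval tibble.
#' @param annotation Gene annotation tibble (see [make_toy_annotation()]).
#' @return Tibble with one row per input interval (same order): `chrom`,
#'   `start`, `end`, `gene` (first tied gene), `genes` (list column of all
#'   tied genes), `distance`.
#' @export
closest_feature <- function(intervals, annotation) {
  intervals <- validate_intervals(intervals)
  genes <- dplyr::filter(as_tibble(annotation), .data$feature == "gene")
  if (nrow(genes) == 0) abort("annotation contains no genes")
  out <- intervals[, c("chrom", "start", "end")]
  out$gene <- NA_character_
  out$genes <- vector("list", nrow(out))
  out$distance <- NA_integer_
  if (nrow(out) == 0) return(out)
  gr_x <- intervals_to_granges(intervals)
  gr_g <- intervals_to_granges(genes)
  # all same-chromosome interval x gene pairs; ties must all be reported,
  # which distanceToNearest() does not guarantee
  pairs <- dplyr::inner_join(
    tibble(q = seq_len(nrow(intervals)), chrom = intervals$chrom),
    tibble(s = seq_len(nrow(genes)), chrom = genes$chrom),
    by = "chrom", relationship = "many-to-many")
  if (nrow(pairs)) {
    pairs$distance <- GenomicRanges::distance(gr_x[pairs$q], gr_g[pairs$s],
                                              ignore.strand = TRUE)
    pairs$gene <- genes$gene_id[pairs$s]
    nearest <- pairs %>%
      group_by(.data$q) %>%
      filter(.data$distance == min(.data$distance)) %>%
      ungroup() %>%
      arrange(.data$q, .data$gene)
    by_q <- split(nearest, nearest$q)
    for (nm in names(by_q)) {
      i <- as.integer(nm)
      out$genes[[i]] <- by_q[[nm]]$gene
      out$gene[i] <- by_q[[nm]]$gene[1]
      out$distance[i] <- as.integer(by_q[[nm]]$distance[1])
    }
  }
  out
}

# region classes in tie-break precedence order
region_classes <- c("cds", "five_utr", "three_utr", "intron")

#' Assign each interval a genic region class
#'
#' Each interval overlapping the annotation is assigned a single class by
#' (i) the class with the most overlapped bases and (ii), on exact ties,
#' the precedence CDS > 5'UTR > 3'UTR > intron.  Intervals with no
#' annotated overlap are classed `NA` (intergenic).
#'
#' @inheritParams closest_feature
#' @return The interval tibble with an added `region` factor column.
#' @export
genic_region_assign <- function(intervals, annotation) {
  intervals <- validate_intervals(intervals)
  ann <- as_tibble(annotation)
  out <- intervals
  out$region <- factor(rep(NA_character_, nrow(out)),
                       levels = region_classes)
  if (nrow(out) == 0) return(out)
  gr_x <- intervals_to_granges(intervals)
  ov_bases <- matrix(0L, nrow = nrow(intervals),
                     ncol = length(region_classes),
                     dimnames = list(NULL, region_classes))
  for (cls in region_classes) {
    feats <- dplyr::filter(ann, .data$feature == cls)
    if (nrow(feats) == 0) next
    gr_f <- intervals_to_granges(feats)
    hits <- GenomicRanges::findOverlaps(gr_x, gr_f, ignore.strand = TRUE)
    if (!length(hits)) next
    w <- GenomicRanges::width(IRanges::pintersect(
      gr_x[S4Vectors::queryHits(hits)], gr_f[S4Vectors::subjectHits(hits)]))
    per_q <- tapply(w, S4Vectors::queryHits(hits), sum)
    ov_bases[as.integer(names(per_q)), cls] <- as.integer(per_q)
  }
  any_ov <- rowSums(ov_bases) > 0
  if (any(any_ov)) {
    # max.col with ties.method = "first" implements the precedence order
    # because columns are laid out in precedence order
    pick <- max.col(ov_bases[any_ov, , drop = FALSE], ties.method = "first")
    out$region[any_ov] <- region_classes[pick]
  }
  out
}

#' Genic region proportions of an interval set
#'
#' Proportion of intervals assigned to each genic region class by
#' [genic_region_assign()].  Intergenic intervals (no annotated overlap)
#' are excluded from the denominator, matching the convention of reporting
#' proportions only over clusters that map to annotated regions.
#'
#' @inheritParams closest_feature
#' @return Tibble with columns `region`, `n`, `proportion` (one row per
#'   region class; proportions sum to 1 over assigned intervals).
#'   Attributes `n_assigned` and `n_intergenic` carry the denominators;
#'   with no assigned interval the proportions are `NaN` and the attribute
#'   `zero_denominator` is `TRUE`.
#' @export
genic_region_proportions <- function(intervals, annotation) {
  assigned <- genic_region_assign(intervals, annotation)
  tab <- table(assigned$region)
  n_assigned <- sum(tab)
  out <- tibble(region = factor(names(tab), levels = region_classes),
                n = as.integer(tab),
                proportion = as.integer(tab) / n_assigned)
  attr(out, "n_assigned") <- n_assigned
  attr(out, "n_intergenic") <- nrow(assigned) - n_assigned
  attr(out, "zero_denominator") <- n_assigned == 0
  out
}
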
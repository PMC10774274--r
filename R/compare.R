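#' Bound-gene set of a consensus footprint table
#'
#' @param footprints A [consensus_footprints()] result with gene
#'   assignments.
#' @return Sorted character vector of unique bound gene ids (all tied
#'   closest genes included).
#' @export
bound_gene_set <- function(footprints) {
  if (!"genes" %in% names(footprints))
    abort("footprints carry no gene assignments; pass an annotation to consensus_footprints()")
  sort(unique(stats::na.omit(unlist(footprints$genes))))
}

#' Exclusive-region partition of condition gene sets
#'
#' Counts, for every non-empty combination of conditions, the genes bound
#' in exactly those conditions — the exclusive regions of the Venn diagram
#' of bound RNAs — with percentages of the union.
#'
#' @param sets Named list (>= 2 entries) of character vectors of gene ids
#'   per condition.
#' @return Tibble of class `venn_partition` with columns `region` (a
#'   `+`-joined combination label), `conditions` (list column), `n`,
#'   `percent`.  Region counts sum to the union size.  An empty union
#'   yields all-zero counts and the attribute `empty_union = TRUE`.
#' @examples
#' venn_partition(list(naive = c("a", "b", "c"), mild = c("b", "c"),
#'                     severe = c("c", "d")))
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || length(sets) < 2)
    abort("venn_partition needs at least two condition sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    abort("condition sets must be named")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  union_ids <- unique(unlist(sets))
  k <- length(sets)
  combos <- unlist(lapply(seq_len(k), function(m)
    combn(names(sets), m, simplify = FALSE)), recursive = FALSE)
  membership <- vapply(sets, function(s) union_ids %in% s,
                       logical(length(union_ids)))
  if (length(union_ids) == 1) membership <- matrix(membership, nrow = 1,
                                                   dimnames = list(NULL, names(sets)))
  rows <- map(combos, function(cmb) {
    inside <- if (length(union_ids)) {
      rowSums(membership[, cmb, drop = FALSE]) == length(cmb) &
        rowSums(membership[, setdiff(names(sets), cmb), drop = FALSE]) == 0
    } else logical(0)
    tibble(region = paste(cmb, collapse = "+"),
           conditions = list(cmb), n = sum(inside))
  })
  out <- list_rbind(rows)
  total <- length(union_ids)
  out$percent <- if (total) 100 * out$n / total else 0
  attr(out, "union_size") <- total
  attr(out, "empty_union") <- total == 0
  class(out) <- c("venn_partition", class(out))
  out
}

#' Genes common to two footprint methods
#'
#' Intersection of two bound-gene sets (for example the peak-calling and
#' the assembly route of footprint discovery), returned in deterministic
#' sorted order.
#'
#' @param method_a,method_b Character vectors of gene ids.
#' @return Sorted character vector.
#' @export
genes_common <- function(method_a, method_b) {
  sort(intersect(unique(as.character(method_a)),
                 unique(as.character(method_b))))
}

#' Gained and lost footprint regions between two conditions
#'
#' Base-level differences between two consensus footprint sets: `lost` is
#' every part of condition A's footprints absent from condition B, and
#' `gained` the converse.  Fragments inherit the closest-gene assignment
#' of the consensus region they came from, and per-gene base-pair totals
#' summarise the shift in the binding profile.
#'
#' @param cond_a,cond_b [consensus_footprints()] tibbles built on the same
#'   annotation.
#' @return List of class `footprint_delta` with elements `lost`, `gained`
#'   (fragment interval tibbles) and `by_gene` (per-gene tibble with
#'   `lost_bp`, `gained_bp`).
#' @export
footprint_delta <- function(cond_a, cond_b) {
  strip <- function(x) {
    keep <- intersect(c("chrom", "start", "end", "gene"), names(x))
    as_tibble(x)[, keep]
  }
  a <- strip(cond_a)
  b <- strip(cond_b)
  lost <- interval_subtract(a, b)
  gained <- interval_subtract(b, a)
  per_gene <- function(x, col) {
    if (nrow(x) == 0 || !"gene" %in% names(x))
      return(tibble(gene = character(), !!col := integer()))
    x %>%
      mutate(bp = .data$end - .data$start) %>%
      group_by(.data$gene) %>%
      summarise(!!col := sum(.data$bp), .groups = "drop")
  }
  by_gene <- dplyr::full_join(per_gene(lost, "lost_bp"),
                              per_gene(gained, "gained_bp"),
                              by = "gene") %>%
    mutate(across(c("lost_bp", "gained_bp"),
                  ~ dplyr::coalesce(.x, 0L))) %>%
    arrange(.data$gene)
  structure(list(lost = lost, gained = gained, by_gene = by_gene),
            class = "footprint_delta")
}

#' @export
print.footprint_delta <- function(x, ...) {
  cat("<footprint_delta> lost ", nrow(x$lost), " fragments (",
      sum(x$lost$end - x$lost$start), " bp), gained ", nrow(x$gained),
      " fragments (", sum(x$gained$end - x$gained$start), " bp)\n",
      sep = "")
  invisible(x)
}

#' @rdname footprint_delta
#' @param x A `footprint_delta` object.
#' @param ... Unused.
#' @method tidy footprint_delta
#' @export
tidy.footprint_delta <- function(x, ...) x$by_gene

# Altschul-Erickson dinucleotide-preserving shuffle of one sequence:
# a uniform random Eulerian walk over the dinucleotide multigraph, so the
# shuffled sequence has exactly the original dinucleotide counts.
dinuc_shuffle_one <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < 3) return(s)
  verts <- unique(ch)
  edges <- lapply(setNames(verts, verts),
                  function(v) ch[which(ch[-n] == v) + 1])
  last <- ch[n]
  # choose a random last-edge for every vertex except the terminal one,
  # accepting only choices whose last-edge graph lets every vertex reach
  # the terminal vertex (Altschul & Erickson)
  repeat {
    last_edge <- vapply(verts, function(v) {
      e <- edges[[v]]
      if (v == last || length(e) == 0) NA_character_
      else e[sample.int(length(e), 1)]
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(last_edge[[v]])) next
      seen <- character(0)
      cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # shuffle the remaining edges, appending each vertex's last-edge
  walk_edges <- lapply(setNames(verts, verts), function(v) {
    e <- edges[[v]]
    le <- last_edge[[v]]
    if (!is.na(le)) {
      e <- e[-match(le, e)]
      c(sample(e), le)
    } else {
      sample(e)
    }
  })
  out <- character(n)
  out[1] <- ch[1]
  ptr <- setNames(rep(1L, length(verts)), verts)
  cur <- ch[1]
  for (i in 2:n) {
    nxt <- walk_edges[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Motif enrichment against a dinucleotide-preserving shuffle null
#'
#' Counts exact (overlap-allowed) occurrences of a motif in a set of
#' sequences and compares them with counts from per-sequence
#' dinucleotide-preserving shuffles, which hold local composition fixed —
#' the standard null for RNA-binding motifs such as UAG or AGGU.  Reports
#' a z-score against the shuffle distribution and the add-one empirical
#' p-value `(1 + #{shuffle counts >= observed}) / (n_shuffles + 1)`, which
#' is therefore never zero.
#'
#' @param sequences Character vector of sequences, or a tibble with a
#'   `seq` column (as from [simulate_sequences()]).
#' @param motif Motif over A/C/G/T or A/C/G/U (U is mapped to T).
#' @param n_shuffles Number of shuffles (>= 20).
#' @param seed Seed for the shuffles.
#' @return One-row tibble of class `motif_enrichment`: `motif`,
#'   `observed`, `shuffle_mean`, `shuffle_sd`, `z`, `p_empirical`,
#'   `n_shuffles`, `n_sequences`, `n_skipped` (sequences shorter than the
#'   motif are skipped).  The attribute `null_counts` keeps the shuffle
#'   distribution.
#' @export
kmer_enrichment <- function(sequences, motif, n_shuffles = 100, seed = 1) {
  if (is.data.frame(sequences)) sequences <- sequences$seq
  sequences <- toupper(as.character(sequences))
  motif <- gsub("U", "T", toupper(motif))
  if (n_shuffles < 20) abort("use at least 20 shuffles")
  keep <- nchar(sequences) >= nchar(motif)
  n_skipped <- sum(!keep)
  sequences <- sequences[keep]
  if (!length(sequences)) abort("no sequence is at least as long as the motif")
  count_all <- function(seqs)
    sum(Biostrings::vcountPattern(motif, Biostrings::DNAStringSet(seqs)))
  observed <- count_all(sequences)
  null_counts <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(b)
      count_all(vapply(sequences, dinuc_shuffle_one, character(1),
                       USE.NAMES = FALSE)),
      numeric(1))
  })
  mu <- mean(null_counts)
  sdv <- sd(null_counts)
  out <- tibble(motif = motif, observed = observed,
                shuffle_mean = mu, shuffle_sd = sdv,
                z = if (sdv > 0) (observed - mu) / sdv else NA_real_,
                p_empirical = (1 + sum(null_counts >= observed)) /
                  (n_shuffles + 1),
                n_shuffles = n_shuffles,
                n_sequences = length(sequences),
                n_skipped = n_skipped)
  attr(out, "null_counts") <- null_counts
  class(out) <- c("motif_enrichment", class(out))
  out
}
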
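# Brute-force oracles, independent of the package's interval code:
# everything here works on per-base logical masks or exhaustive scans.

# random interval set on a single small chromosome
random_intervals <- function(n, chrom_len = 10000, chrom = "chrT") {
  start <- sample.int(chrom_len - 50, n, replace = TRUE) - 1L
  width <- sample(1:80, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = start,
                 end = pmin(start + width, chrom_len))
}

# per-base coverage mask of an interval set (one chromosome)
mask_of <- function(x, chrom_len) {
  m <- logical(chrom_len)
  for (i in seq_len(nrow(x))) m[(x$start[i] + 1):x$end[i]] <- TRUE
  m
}

# contiguous TRUE runs of a mask, as 0-based half-open intervals
runs_of <- function(m, chrom = "chrT") {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(chrom = chrom, start = starts[keep], end = ends[keep])
}

# per-base subtraction applied to each interval of `a` separately
oracle_subtract <- function(a, b, chrom_len) {
  cover_b <- mask_of(b, chrom_len)
  out <- list()
  for (i in seq_len(nrow(a))) {
    m <- logical(chrom_len)
    m[(a$start[i] + 1):a$end[i]] <- TRUE
    out[[i]] <- runs_of(m & !cover_b, chrom = a$chrom[i])
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start, end)
}

oracle_merge <- function(a, chrom_len) {
  runs_of(mask_of(a, chrom_len), chrom = a$chrom[1])
}

# consensus by direct definition: candidates are the merged union;
# support of a candidate is the best seed replicate present in it plus
# every other replicate with a footprint overlapping one of the seed's
# footprints (in the candidate) by >= min_overlap bases; all arithmetic,
# no interval code
oracle_consensus <- function(replicates, chrom_len, min_support = 2,
                             min_overlap = 2) {
  cand <- oracle_merge(dplyr::bind_rows(replicates), chrom_len)
  in_cand <- function(r, ci)
    r[pmin(cand$end[ci], r$end) - pmax(cand$start[ci], r$start) > 0, ,
      drop = FALSE]
  pair_agrees <- function(ra, rb) {
    for (i in seq_len(nrow(ra))) {
      ov <- pmin(ra$end[i], rb$end) - pmax(ra$start[i], rb$start)
      if (any(ov >= min_overlap)) return(TRUE)
    }
    FALSE
  }
  support <- integer(nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    local <- lapply(replicates, in_cand, ci = ci)
    per_seed <- vapply(seq_along(local), function(r) {
      if (nrow(local[[r]]) == 0) return(0L)
      1L + sum(vapply(seq_along(local), function(s) {
        s != r && nrow(local[[s]]) > 0 && pair_agrees(local[[r]], local[[s]])
      }, logical(1)))
    }, 0L)
    support[ci] <- max(per_seed)
  }
  cand$support <- support
  cand[cand$support >= min_support, , drop = FALSE]
}

# closest genes by arithmetic scan over the 0-based half-open table
oracle_closest <- function(intervals, genes) {
  lapply(seq_len(nrow(intervals)), function(i) {
    g <- genes[genes$chrom == intervals$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(list(genes = NULL, distance = NA_integer_))
    d <- pmax(0L, pmax(g$start - intervals$end[i],
                       intervals$start[i] - g$end))
    sel <- which(d == min(d))
    list(genes = sort(g$gene_id[sel]), distance = min(d))
  })
}

# exhaustive maximum-weight one-to-one matching over an edge list
# (idx1, idx2, weight); feasible because overlap components are tiny
oracle_max_matching <- function(edges) {
  best <- list(weight = 0, edges = integer(0))
  recurse <- function(remaining, used1, used2, w, chosen) {
    if (w > best$weight) best <<- list(weight = w, edges = chosen)
    if (!nrow(remaining)) return()
    for (k in seq_len(nrow(remaining))) {
      e <- remaining[k, ]
      if (e$idx1 %in% used1 || e$idx2 %in% used2) next
      recurse(remaining[-seq_len(k), , drop = FALSE],
              c(used1, e$idx1), c(used2, e$idx2),
              w + e$weight, c(chosen, e$id))
    }
  }
  edges$id <- seq_len(nrow(edges))
  recurse(edges, integer(0), integer(0), 0, integer(0))
  best
}

# exact two-sided Mann-Whitney p by enumeration, computing U by direct
# pair counting (greater-than pairs plus half the ties) instead of ranks
oracle_mw_p <- function(a, b) {
  vals <- c(a, b)
  n1 <- length(a)
  n <- length(vals)
  u_of <- function(idx) {
    x <- vals[idx]
    y <- vals[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  mid <- n1 * (n - n1) / 2
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2, u_of)
  mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-9)
}

# dinucleotide counts of a sequence
dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}
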
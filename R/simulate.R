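#' Build a toy gene annotation
#'
#' Places `n_genes` non-overlapping gene models on the scenario's toy
#' chromosomes.  Each gene carries a 5'UTR, 2-4 CDS exons separated by
#' introns, and a 3'UTR (feature order reversed in genomic coordinates on
#' the minus strand), with intergenic space between genes.  Purely a
#' structural stand-in for a reference annotation: feature widths are drawn
#' from bounded uniform ranges, and no sequence content is implied.
#'
#' @param scenario A [clip_scenario()].
#' @param seed Optional seed overriding the scenario's annotation
#'   substream.
#' @return A tibble of class `clip_annotation` with columns `gene_id`,
#'   `chrom`, `strand`, `feature` (`gene`, `five_utr`, `cds`, `intron`,
#'   `three_utr`), `start`, `end` (BED convention), plus a `chrom_lengths`
#'   attribute.
#' @examples
#' ann <- make_toy_annotation(clip_scenario(seed = 1, n_genes = 5))
#' dplyr::count(ann, feature)
#' @export
make_toy_annotation <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "clip_scenario"))
  seed <- seed %||% derive_seed(scenario$seed, "annotation")
  chrom_lengths <- setNames(rep(scenario$chrom_length, scenario$n_chroms),
                            paste0("chr", seq_len(scenario$n_chroms)))
  empty <- tibble(gene_id = character(), chrom = character(),
                  strand = character(), feature = character(),
                  start = integer(), end = integer())
  if (scenario$n_genes == 0) {
    attr(empty, "chrom_lengths") <- chrom_lengths
    class(empty) <- c("clip_annotation", class(empty))
    return(empty)
  }
  withr::with_seed(seed, {
    rows <- vector("list", scenario$n_genes)
    chrom_i <- 1L
    cursor <- 0L
    for (g in seq_len(scenario$n_genes)) {
      n_cds <- sample(2:4, 1)
      widths <- c(five_utr = sample(60:150, 1))
      for (k in seq_len(n_cds)) {
        widths <- c(widths, setNames(sample(80:250, 1), "cds"))
        if (k < n_cds)
          widths <- c(widths, setNames(sample(200:1000, 1), "intron"))
      }
      widths <- c(widths, three_utr = sample(100:300, 1))
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") widths <- rev(widths)
      gap <- sample(200:2000, 1)
      gene_len <- sum(widths)
      # advance to a chromosome with room for gap + gene
      while (chrom_i <= length(chrom_lengths) &&
             cursor + gap + gene_len > chrom_lengths[chrom_i]) {
        chrom_i <- chrom_i + 1L
        cursor <- 0L
      }
      if (chrom_i > length(chrom_lengths))
        abort(paste0("cannot place ", scenario$n_genes,
                     " genes without overlap on the toy genome"))
      gene_start <- cursor + gap
      starts <- gene_start + cumsum(c(0L, head(unname(widths), -1)))
      rows[[g]] <- tibble(
        gene_id = sprintf("gene%03d", g),
        chrom = names(chrom_lengths)[chrom_i],
        strand = strand,
        feature = names(widths),
        start = as.integer(starts),
        end = as.integer(starts + widths))
      cursor <- gene_start + gene_len
    }
    ann <- bind_rows(rows)
    gene_rows <- ann %>%
      group_by(.data$gene_id, .data$chrom, .data$strand) %>%
      summarise(feature = "gene", start = min(.data$start),
                end = max(.data$end), .groups = "drop")
    ann <- bind_rows(gene_rows, ann) %>%
      arrange(.data$chrom, .data$start, dplyr::desc(.data$feature == "gene"))
    attr(ann, "chrom_lengths") <- chrom_lengths
    class(ann) <- c("clip_annotation", class(ann))
    ann
  })
}

#' Chromosome lengths of a toy annotation
#' @param annotation A `clip_annotation`.
#' @return Named integer vector of chromosome lengths.
#' @export
chrom_lengths <- function(annotation) {
  cl <- attr(annotation, "chrom_lengths")
  if (is.null(cl)) abort("annotation carries no chrom_lengths attribute")
  cl
}

#' Simulate true protein-bound sites
#'
#' Samples `n_true_sites` intervals, each placed fully inside a feature of
#' a genic region class drawn from `region_bias` (intron-heavy by default,
#' mirroring intron-dominant RNA binding), with widths uniform over
#' `site_width_range`.
#'
#' @inheritParams make_toy_annotation
#' @param annotation Annotation from [make_toy_annotation()].
#' @return Interval tibble with columns `chrom`, `start`, `end`, `name`
#'   (site id) and `region` (the sampled class).
#' @export
simulate_true_sites <- function(annotation, scenario, seed = NULL) {
  stopifnot(inherits(scenario, "clip_scenario"))
  seed <- seed %||% derive_seed(scenario$seed, "true_sites")
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), region = character())
  if (scenario$n_true_sites == 0) return(empty)
  feats <- as_tibble(annotation) %>%
    filter(.data$feature %in% region_classes) %>%
    mutate(width = .data$end - .data$start)
  withr::with_seed(seed, {
    classes <- sample(names(scenario$region_bias), scenario$n_true_sites,
                      replace = TRUE, prob = scenario$region_bias)
    wlo <- scenario$site_width_range[1]
    whi <- scenario$site_width_range[2]
    rows <- vector("list", scenario$n_true_sites)
    for (i in seq_len(scenario$n_true_sites)) {
      pool <- feats[feats$feature == classes[i], ]
      if (nrow(pool) == 0)
        abort(paste0("annotation has no features of class ", classes[i]))
      placed <- FALSE
      for (try in 1:100) {
        w <- sample(wlo:whi, 1)
        fit <- pool[pool$width >= w, ]
        if (nrow(fit) == 0) next
        f <- fit[sample.int(nrow(fit), 1, prob = fit$width), ]
        s <- f$start + sample.int(f$width - w + 1L, 1) - 1L
        rows[[i]] <- tibble(chrom = f$chrom, start = as.integer(s),
                            end = as.integer(s + w),
                            name = sprintf("site%05d", i),
                            region = classes[i])
        placed <- TRUE
        break
      }
      if (!placed)
        abort(paste0("could not place a site of class ", classes[i],
                     " after 100 tries; features too small"))
    }
    bind_rows(rows)
  })
}

# equicorrelated multivariate normal latent scores: one row per site,
# one column per replicate
equicorr_normal <- function(n, n_reps, mean, sd, rho) {
  shared <- rnorm(n)
  indep <- matrix(rnorm(n * n_reps), nrow = n)
  mean + sd * (sqrt(rho) * shared + sqrt(1 - rho) * indep)
}

#' Simulate per-replicate scored peak sets
#'
#' For each true site retained under the condition's loss fraction, the
#' site is reproducible with probability `pi1`: all replicates then receive
#' a peak there with latent scores from the correlated signal component
#' (mean `mu1`, sd `sigma1`, pairwise correlation `rho1`).  Otherwise the
#' replicates still carry the peak but with independent standard-normal
#' (null) latent scores.  Each replicate additionally receives unmatched
#' noise peaks with null scores.  Scores are emitted both as positive reals
#' (`score = exp(latent)`) and as integer read-support counts
#' (`support ~ Poisson(exp(latent))`), so that peak-level pseudo-replicate
#' thinning is well defined.
#'
#' @inheritParams simulate_true_sites
#' @param true_sites Output of [simulate_true_sites()].
#' @param n_reps Number of replicates to generate.
#' @param condition Condition label; must name an entry of the scenario's
#'   `condition_loss`.
#' @return List of interval tibbles (one per replicate) with columns
#'   `chrom`, `start`, `end`, `name`, `score`, `support` and attributes
#'   `sample_id` and `condition`.
#' @export
simulate_replicate_peaks <- function(true_sites, scenario, n_reps,
                                     condition = "naive", seed = NULL) {
  stopifnot(inherits(scenario, "clip_scenario"), n_reps >= 1)
  if (!condition %in% names(scenario$condition_loss))
    abort(paste0("unknown condition: ", condition))
  seed <- seed %||% derive_seed(scenario$seed, paste0("peaks_", condition))
  loss <- scenario$condition_loss[[condition]]
  chroms <- paste0("chr", seq_len(scenario$n_chroms))
  withr::with_seed(seed, {
    n_sites <- nrow(true_sites)
    keep <- if (n_sites) runif(n_sites) >= loss else logical(0)
    sites <- true_sites[keep, , drop = FALSE]
    n_kept <- nrow(sites)
    repro <- if (n_kept) runif(n_kept) < scenario$pi1 else logical(0)
    latent <- matrix(rnorm(n_kept * n_reps), nrow = n_kept)
    if (any(repro)) {
      latent[repro, ] <- equicorr_normal(sum(repro), n_reps,
                                         scenario$mu1, scenario$sigma1,
                                         scenario$rho1)
    }
    reps <- vector("list", n_reps)
    wlo <- scenario$site_width_range[1]
    whi <- scenario$site_width_range[2]
    for (r in seq_len(n_reps)) {
      if (n_kept) {
        jit_s <- sample(0:5, n_kept, replace = TRUE)
        jit_e <- sample(0:5, n_kept, replace = TRUE)
        matched <- tibble(
          chrom = sites$chrom,
          start = pmax(0L, sites$start - jit_s),
          end = as.integer(sites$end + jit_e),
          name = sites$name,
          reproducible = repro,
          latent = latent[, r])
      } else {
        matched <- tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          reproducible = logical(), latent = double())
      }
      n_noise <- scenario$n_noise_peaks_per_rep
      if (n_noise > 0) {
        w <- sample(wlo:whi, n_noise, replace = TRUE)
        chrom <- sample(chroms, n_noise, replace = TRUE)
        s <- floor(runif(n_noise, 0, scenario$chrom_length - w))
        noise <- tibble(chrom = chrom, start = as.integer(s),
                        end = as.integer(s + w),
                        name = sprintf("noise_r%d_%05d", r, seq_len(n_noise)),
                        reproducible = FALSE,
                        latent = rnorm(n_noise))
      } else {
        noise <- matched[0, ]
      }
      peaks <- bind_rows(matched, noise) %>%
        mutate(score = exp(.data$latent),
               support = rpois(dplyr::n(), exp(.data$latent))) %>%
        select(-"latent") %>%
        arrange(.data$chrom, .data$start, .data$end)
      attr(peaks, "sample_id") <- paste0(condition, "_rep", r)
      attr(peaks, "condition") <- condition
      reps[[r]] <- peaks
    }
    reps
  })
}

#' Simulate a background interval track
#'
#' Draws a Poisson number of background intervals (rate
#' `background_rate` per kilobase of genome) placed uniformly — the
#' stand-in for the size-matched input / pooled IgG control whose sites
#' are depleted from each immunoprecipitation sample.
#'
#' @inheritParams simulate_true_sites
#' @return Interval tibble with columns `chrom`, `start`, `end`, `name`.
#' @export
simulate_background <- function(annotation, scenario, seed = NULL) {
  stopifnot(inherits(scenario, "clip_scenario"))
  seed <- seed %||% derive_seed(scenario$seed, "background")
  cl <- chrom_lengths(annotation)
  withr::with_seed(seed, {
    genome_kb <- sum(cl) / 1000
    n <- rpois(1, scenario$background_rate * genome_kb)
    if (n == 0)
      return(tibble(chrom = character(), start = integer(),
                    end = integer(), name = character()))
    wlo <- scenario$site_width_range[1]
    whi <- scenario$site_width_range[2]
    w <- sample(wlo:whi, n, replace = TRUE)
    chrom <- sample(names(cl), n, replace = TRUE, prob = cl)
    s <- floor(runif(n, 0, cl[chrom] - w))
    arrange(tibble(chrom = chrom, start = as.integer(s),
                   end = as.integer(s + w),
                   name = sprintf("bg%05d", seq_len(n))),
            .data$chrom, .data$start, .data$end)
  })
}

#' Simulate footprint sequences with a planted motif
#'
#' Generates one uniform-composition sequence per footprint and plants
#' extra motif occurrences so that the expected occurrence rate equals
#' `motif_enrichment` times the background expectation
#' `(L - k + 1) / 4^k` of a uniform sequence.  Motifs given in the RNA
#' alphabet are mapped U to T and matched against DNA-alphabet sequences.
#'
#' @inheritParams simulate_true_sites
#' @param footprints Interval tibble; widths set sequence lengths.
#' @return Tibble with columns `name` and `seq` (DNA alphabet).
#' @export
simulate_sequences <- function(footprints, scenario, seed = NULL) {
  stopifnot(inherits(scenario, "clip_scenario"))
  seed <- seed %||% derive_seed(scenario$seed, "sequences")
  motif <- gsub("U", "T", toupper(scenario$motif))
  k <- nchar(motif)
  widths <- footprints$end - footprints$start
  if (any(widths < k))
    abort("motif longer than the shortest footprint")
  names <- if ("name" %in% names(footprints) &&
               !anyNA(footprints$name)) {
    footprints$name
  } else {
    sprintf("fp%05d", seq_len(nrow(footprints)))
  }
  withr::with_seed(seed, {
    seqs <- vapply(widths, function(w)
      paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
            collapse = ""), character(1))
    extra_rate <- (scenario$motif_enrichment - 1) *
      (widths - k + 1) / 4^k
    n_plant <- rpois(length(widths), extra_rate)
    for (i in which(n_plant > 0)) {
      pos <- sample.int(widths[i] - k + 1L, min(n_plant[i], widths[i] - k + 1L),
                        replace = FALSE)
      s <- strsplit(seqs[i], "")[[1]]
      for (p in pos) s[p:(p + k - 1)] <- strsplit(motif, "")[[1]]
      seqs[i] <- paste(s, collapse = "")
    }
    tibble(name = names, seq = seqs)
  })
}

#' Simulate companion assay tables
#'
#' Generates the three validation-assay inputs: a junction-count table
#' (per-sample inclusion counts binomial at the group's length-adjusted
#' inclusion probability, so [psi()] recovers the planted PSI), a qPCR Ct
#' table whose target-vs-reference shifts encode the planted per-group
#' fold changes, and a band-intensity table with multiplicative log-normal
#' noise of the stated coefficient of variation.
#'
#' @inheritParams make_toy_annotation
#' @param inclusion_length,skipping_length Effective lengths of the
#'   inclusion and skipping junction forms (defaults 2 and 1, the usual
#'   skipped-exon junction counting).
#' @return List of three tibbles: `junctions` (`sample_id`, `group`,
#'   `event_id`, `inclusion`, `skipping`, `inclusion_length`,
#'   `skipping_length`), `ct` (`sample_id`, `group`, `ct_target`,
#'   `ct_reference`), `bands` (`sample_id`, `group`, `band_a`, `band_b`).
#' @export
simulate_assay_tables <- function(scenario, seed = NULL,
                                  inclusion_length = 2L,
                                  skipping_length = 1L) {
  stopifnot(inherits(scenario, "clip_scenario"))
  if (scenario$junction_depth < 1) abort("junction_depth must be >= 1")
  seed <- seed %||% derive_seed(scenario$seed, "assays")
  groups <- names(scenario$psi_by_group)
  n <- scenario$n_per_group
  withr::with_seed(seed, {
    samples <- tibble(
      group = rep(groups, each = n),
      sample_id = paste0(rep(groups, each = n), "_s", rep(seq_len(n),
                                                          length(groups))))
    psi <- scenario$psi_by_group[samples$group]
    # length normalization applied in reverse: reads land on the inclusion
    # form proportionally to psi * effective length
    p_inc <- psi * inclusion_length /
      (psi * inclusion_length + (1 - psi) * skipping_length)
    inc <- rbinom(nrow(samples), scenario$junction_depth, p_inc)
    junctions <- mutate(samples,
                        event_id = "event1",
                        inclusion = inc,
                        skipping = scenario$junction_depth - inc,
                        inclusion_length = inclusion_length,
                        skipping_length = skipping_length)
    folds <- scenario$fold_by_group[samples$group]
    ct_ref <- rnorm(nrow(samples), mean = 18, sd = 0.15)
    # base delta-Ct 6 cycles; a fold change f shifts delta-Ct by -log2(f)
    ct <- mutate(samples,
                 ct_reference = ct_ref,
                 ct_target = ct_ref + 6 - log2(folds) +
                   rnorm(nrow(samples), sd = 0.05))
    frac <- scenario$psi_by_group[samples$group]
    noise <- function() exp(rnorm(nrow(samples), sd = scenario$band_cv))
    bands <- mutate(samples,
                    band_a = 1000 * frac * noise(),
                    band_b = 1000 * (1 - frac) * noise())
    list(junctions = junctions, ct = ct, bands = bands)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
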
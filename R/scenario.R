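#' Define a synthetic CLIP-seq scenario
#'
#' A scenario bundles every tunable of the synthetic-data generators: the toy
#' genome, the true binding-site model, the two-component (reproducible vs
#' irreproducible) replicate score model that the IDR analysis assumes, the
#' per-condition loss of binding sites, background contamination, motif
#' planting, and the companion splicing/qPCR assay settings.  All generators
#' are pure functions of `(scenario, seed)`: rerunning with the same scenario
#' and seed reproduces identical output.
#'
#' The defaults describe the study conditions this package emulates: three
#' disease groups (`naive`, `mild`, `severe`; replicate counts 3/3/4) where
#' severe disease loses half of the unique binding sites, intron-dominant
#' binding, a planted UAG motif, and a reproducible score component with
#' mixing weight `pi1 = 0.65`, latent mean `mu1 = 2.5`, sd `sigma1 = 1` and
#' pairwise correlation `rho1 = 0.8`.
#'
#' @param seed Integer root seed; every generator derives its own substream
#'   from it.
#' @param n_chroms,chrom_length Number and length (nt) of toy chromosomes.
#' @param n_genes Number of non-overlapping gene models to place.
#' @param n_true_sites Number of true protein-bound sites to simulate.
#' @param region_bias Named probabilities (summing to 1) over the genic
#'   region classes `five_utr`, `cds`, `intron`, `three_utr` from which true
#'   sites are drawn.
#' @param pi1 Probability that a retained true site is *reproducible*, i.e.
#'   its replicate scores come from the correlated signal component.
#' @param mu1,sigma1 Mean and sd of the latent signal score (the
#'   irreproducible/null component is standard normal).
#' @param rho1 Pairwise correlation of signal scores across replicates, in
#'   `[0, 1)`.
#' @param n_noise_peaks_per_rep Unmatched noise peaks added per replicate.
#' @param background_rate Background intervals per kilobase (Poisson rate)
#'   for the size-matched input / IgG control track.
#' @param condition_loss Named fractions in `[0, 1]`: per condition, the
#'   fraction of true sites removed before replicates are generated.
#' @param n_reps_by_condition Named integer replicate counts per condition.
#' @param site_width_range Length-2 integer range (nt) of site widths,
#'   sampled uniformly.
#' @param motif Motif string over A/C/G/U or A/C/G/T planted into footprint
#'   sequences (RNA alphabet is mapped U to T).
#' @param motif_enrichment Fold enrichment (>= 1) of the motif occurrence
#'   rate over the uniform-background expectation.
#' @param junction_depth Junction read depth per sample for splice-event
#'   simulation.
#' @param psi_by_group Named true percent-spliced-in per assay group.
#' @param fold_by_group Named true qPCR fold changes per group (the first
#'   group is the calibrator and should be 1).
#' @param band_cv Coefficient of variation of multiplicative noise on
#'   simulated band intensities.
#' @param n_per_group Samples per group in the simulated assay tables.
#'
#' @return An object of class `clip_scenario` (a named list).
#' @examples
#' sc <- clip_scenario(seed = 1, n_genes = 10, n_true_sites = 50)
#' sc$pi1
#' @export
clip_scenario <- function(seed = 1L,
                          n_chroms = 2L,
                          chrom_length = 600000L,
                          n_genes = 200L,
                          n_true_sites = 300L,
                          region_bias = c(intron = 0.6, cds = 0.2,
                                          three_utr = 0.1, five_utr = 0.1),
                          pi1 = 0.65,
                          mu1 = 2.5,
                          sigma1 = 1,
                          rho1 = 0.8,
                          n_noise_peaks_per_rep = 100L,
                          background_rate = 0.2,
                          condition_loss = c(naive = 0, mild = 0.15,
                                             severe = 0.5),
                          n_reps_by_condition = c(naive = 3L, mild = 3L,
                                                  severe = 4L),
                          site_width_range = c(20L, 60L),
                          motif = "UAG",
                          motif_enrichment = 5,
                          junction_depth = 2000L,
                          psi_by_group = c(control = 0.7, case = 0.4),
                          fold_by_group = c(control = 1, case = 0.5),
                          band_cv = 0.1,
                          n_per_group = 5L) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (n_chroms < 1 || chrom_length < 1000)
    abort("need at least one chromosome of >= 1000 nt")
  if (n_genes < 0 || n_true_sites < 0 || n_noise_peaks_per_rep < 0)
    abort("counts must be non-negative")
  bad_class <- setdiff(names(region_bias),
                       c("five_utr", "cds", "intron", "three_utr"))
  if (length(bad_class))
    abort(paste0("unknown region class: ", paste(bad_class, collapse = ", ")))
  if (abs(sum(region_bias) - 1) > 1e-8)
    abort("region_bias must sum to 1")
  if (any(region_bias < 0)) abort("region_bias must be non-negative")
  if (n_true_sites > 0 && (pi1 <= 0 || pi1 >= 1))
    abort("pi1 must lie in (0, 1) when reproducible peaks are requested")
  if (mu1 <= 0 || sigma1 <= 0) abort("mu1 and sigma1 must be positive")
  if (rho1 < 0 || rho1 >= 1) abort("rho1 must lie in [0, 1)")
  if (background_rate < 0) abort("background_rate must be >= 0")
  if (any(condition_loss < 0 | condition_loss > 1))
    abort("condition_loss fractions must lie in [0, 1]")
  if (!all(names(condition_loss) %in% names(n_reps_by_condition)))
    abort("every condition needs a replicate count in n_reps_by_condition")
  if (any(site_width_range < 1) || site_width_range[1] > site_width_range[2])
    abort("invalid site_width_range")
  if (!nzchar(motif)) abort("motif must be a non-empty string")
  if (motif_enrichment < 1) abort("motif_enrichment must be >= 1")
  if (junction_depth < 1) abort("junction_depth must be >= 1")
  if (any(psi_by_group < 0 | psi_by_group > 1))
    abort("psi_by_group entries must be probabilities")
  if (any(fold_by_group <= 0)) abort("fold_by_group entries must be > 0")

  structure(
    list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
         chrom_length = as.integer(chrom_length),
         n_genes = as.integer(n_genes),
         n_true_sites = as.integer(n_true_sites),
         region_bias = region_bias, pi1 = pi1, mu1 = mu1, sigma1 = sigma1,
         rho1 = rho1,
         n_noise_peaks_per_rep = as.integer(n_noise_peaks_per_rep),
         background_rate = background_rate, condition_loss = condition_loss,
         n_reps_by_condition = n_reps_by_condition,
         site_width_range = as.integer(site_width_range),
         motif = toupper(motif), motif_enrichment = motif_enrichment,
         junction_depth = as.integer(junction_depth),
         psi_by_group = psi_by_group, fold_by_group = fold_by_group,
         band_cv = band_cv, n_per_group = as.integer(n_per_group)),
    class = "clip_scenario")
}

#' @export
print.clip_scenario <- function(x, ...) {
  cat("<clip_scenario>\n")
  cat("  genome: ", x$n_chroms, " chrom x ", x$chrom_length, " nt, ",
      x$n_genes, " genes\n", sep = "")
  cat("  sites:  ", x$n_true_sites, " true sites, pi1 = ", x$pi1,
      ", rho1 = ", x$rho1, "\n", sep = "")
  cat("  conditions: ",
      paste0(names(x$condition_loss), " (loss ", x$condition_loss, ")",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}
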
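---
title: "Models and methods behind clipfoot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clipfoot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipfoot)
```

clipfoot implements the downstream computations of a CLIP-seq study of an
RNA-binding protein across disease conditions: footprint construction from
scored interval sets, reproducibility assessment with the IDR copula
mixture, condition-level binding-profile comparison, and the companion
splicing/qPCR assay quantifications.  This vignette explains the models,
the choices that were genuinely open, and what the synthetic data do and
do not establish.

## Footprint construction

Intervals are BED-convention tibbles: 0-based, half-open, a choice made
once for the whole package because BED is the interchange format of the
upstream peak callers.  Subtraction and merging are strand-agnostic by
default, matching the default settings of the interval tools this layer
mirrors; strand-aware behaviour is available via `ignore_strand = FALSE`.

Background depletion removes, base by base, everything recovered in the
size-matched input or IgG control; merging combines overlapping *and
book-ended* intervals (`gap = 0`).  Both operations are checked in the
test suite against per-base boolean-mask oracles on hundreds of random
small instances.

**Consensus semantics.** A consensus candidate is a maximal merged region
of the union of all replicate footprints (the union, not a reference
replicate, so no sample is privileged).  Support counts cross-sample
agreement: replicate *r* agrees with replicate *s* on a candidate when a
footprint of one overlaps a footprint of the other by at least
`min_overlap` nt, and the candidate's support is the best "seed"
replicate plus all replicates agreeing with it.  This is the reading
under which a 1-nt overlap between two samples does *not* make a
footprint consistent — "more than 1 nt" is taken strictly, so the default
is `min_overlap = 2` — while any footprint trivially overlaps the
candidate it seeded.  `min_support` defaults to 2 for groups of 3 or 4
alike, exactly the printed majority rule.  The retained region is the
merged union, not the intersection: downstream use is gene-level, and the
broader region is the safer representation for closest-gene assignment.

**Closest gene and genic regions.** Distance is the number of bases
between closest span edges (0 when overlapping); exact ties return all
tied genes in lexicographic order, so results are deterministic.  Genic
region classes are assigned by majority of overlapped bases with the
precedence CDS > 5′UTR > 3′UTR > intron on exact ties — the precedence is
a documented convention (coding evidence outranks regulatory, regulatory
outranks intronic), not an empirical claim.  Intergenic intervals are
excluded from the proportion denominator, mirroring the convention of
reporting proportions over clusters mapping to annotated regions.

## The IDR model

For a matched pair of replicate score vectors, each margin is
rank-transformed with midranks and mapped through the empirical CDF with
the n/(n+1) correction.  Pseudo-data are obtained by inverting the
current mixture marginal
$G(z) = \pi_1 N(z;\mu_1,\sigma_1^2) + (1-\pi_1) N(z;0,1)$
(numerically, on a 4000-point grid with monotone interpolation — the
grid spans all quantiles the ECDF can produce, so no extrapolation
occurs).  The copula mixture has a standard bivariate normal null with
correlation 0 and a signal component with mean $(\mu_1,\mu_1)$, variance
$\sigma_1^2$ and correlation $\rho_1$.  Each EM iteration refreshes the
pseudo-data from the current parameters and takes one E+M step, with
constraint boxes $\pi_1 \in [10^{-4}, 1-10^{-4}]$, $\mu_1 \ge 0.01$,
$\sigma_1^2 \ge 10^{-4}$, $\rho_1 \in [0, 0.999]$.  Initialisation is
fixed at $(\pi_1,\mu_1,\sigma_1,\rho_1) = (0.5, 1, 1, 0.5)$; no random
restarts, so the fit is a deterministic function of the input ranks, and
any strictly monotone transform of either replicate's scores leaves the
result unchanged (verified in the tests by exponentiating one margin).

**Why the EM is capped.** The fit stops on a parameter plateau
(`tol = 1e-4`) or after `max_iter = 100` iterations, whichever comes
first, and reports `converged = FALSE` at the cap.  Running this EM to
full stationarity is deliberately avoided for two reasons.  First,
$\sigma_1$ approaches its limit only logarithmically while the useful
estimates ($\pi_1$, $\rho_1$) stabilise within a few dozen iterations.
Second, on signal-free data the mixture likelihood is maximised by a
degenerate solution in which an uncorrelated "signal" component absorbs
the null and every pair passes any IDR threshold; the capped EM stays
away from that collapse, which is what makes the null calibration hold
(with $\pi_1 = 0$ data, essentially no pairs pass global IDR 0.05).  A
`converged = FALSE` flag on an otherwise healthy fit is therefore
expected behaviour, not a failure.  Duplicated scores (one replicate a
copy of the other) drive $\rho_1$ to the 0.999 boundary, which is
reported rather than masked.

The local idr of a pair is its posterior null probability at the final
parameters; the global IDR is the running mean of local idr in ascending
order — the expected irreproducible fraction among all pairs called at
least as reproducible.  `count_passing()` applies the threshold to the
global IDR; 0.05 is the exposed default since the upstream study does not
print its cutoff.  The score column fed to the fit is likewise a
parameter: the study does not state whether peak height or significance
was used, so the simulator emits a generic positive score.

## Rescue and self-consistency ratios

Pseudo-replicates are built at peak level: each peak's integer read
support is split Binomial(support, 1/2), and each half keeps its peaks
with nonzero support.  This preserves the intent of read-splitting
(halved evidence) without requiring reads, which do not exist at desk
scale.  The four counts are `n_true` (true replicate pair), `n_pooled`
(pooled peaks, support summed over overlapping peaks, then pseudo-split)
and `n_self_1`/`n_self_2` (each replicate's own split).  One split
stream is used for both replicates of a pair, keeping the construction
symmetric — identical replicates receive identical splits and a
self-consistency ratio of exactly 1.

Acceptability follows the printed criterion strictly: either ratio
strictly below 2 (a ratio of exactly 2 fails).  For outlier detection the
package additionally records `strict_pass` — both ratios below 2, the
full-pass tier of the ENCODE standard — and the pairwise group summary
flags samples failing (not strictly passing) a majority of their pairs.
The distinction matters: a replicate of pure independent noise keeps an
unremarkable self-consistency ratio at peak level (its split halves
remain coupled through the support counts) while its rescue ratio
degenerates, so under the either-ratio rule alone it would never be
flagged.  A sub-fit with fewer than 50 matched pairs refuses to estimate
(the mixture is unstable below that); the affected count becomes `NA`,
the ratio `NA`, the pair not acceptable, and the failure is recorded in
the report's `errors` attribute.

The pairwise design itself mirrors the study's workaround for the
two-replicate limitation of the IDR model: every unordered pair within a
condition is analysed separately.

## Profile comparison and motif null

Bound-gene partitions are exact exclusive-region counts over all
non-empty condition combinations; counts always sum to the union size,
and label permutations permute but never change counts.  Footprint deltas
are base-level subtractions in both directions, with fragments inheriting
the closest-gene assignment of the consensus region they came from (more
stable than re-assigning each fragment).

The motif null preserves dinucleotide content exactly via the
Altschul–Erickson Eulerian-walk shuffle, the standard null for RNA motifs
because it holds local composition (e.g. AG-richness) fixed;
mononucleotide shuffling would overstate enrichment of composition-biased
motifs.  Occurrences are counted with overlaps allowed; the empirical p
uses the add-one rule (1 + #{null ≥ observed})/(n_shuffles + 1) and is
therefore never zero; motifs in the RNA alphabet are matched after U→T
mapping.  This k-mer test is an explicit stand-in for full motif-suite
analyses (no PWM learning, no width search).

## Assay quantification

PSI uses the effective-length-normalised form
$(I/l_I)\,/\,(I/l_I + S/l_S)$; ΔPSI is mean control PSI minus mean case
PSI, so positive values mean higher inclusion in controls.  ΔΔCt uses
the arithmetic mean of calibrator ΔCt (the usual convention; the choice
is exposed), which makes the calibrator's fold changes geometric-mean 1
by construction.  The exact Mann–Whitney test enumerates all
$\binom{n_1+n_2}{n_1}$ assignments of the observed values (midranks on
ties) and counts assignments at least as far from $n_1 n_2/2$ as
observed — at the figure scale (n = 3 vs 5) this gives p = 2/56 ≈ 0.0357
for complete separation.  Enumeration is capped at combined n = 20; the
one-tailed t tests expose both Welch and pooled-variance forms because
the study does not state which was used.

## What the synthetic data emulate — and what they do not

The generators reproduce the statistical *structure* the analysis
assumes: a two-component score model with equicorrelated signal latents
(π₁ = 0.65, μ₁ = 2.5, σ₁ = 1, ρ₁ = 0.8 by default — the generative
settings used throughout the recovery checks; the study itself prints no
such values), integer supports as Poisson(exp(latent)) so pseudo-replicate
thinning is well defined, per-condition site loss (naive 0, mild 0.15,
severe 0.5) over groups of 3/3/4 replicates mirroring the clinical-score
grouping (severe ≥ 2.5, mild 1.0–2.0), intron-dominant region bias
(intron 0.6, CDS 0.2, UTRs 0.1 each), uniform-composition sequences with
planted UAG at a configurable fold, and binomial junction counts whose
inclusion probability is the length-adjusted PSI.  The default toy genome
(2 × 600 kb, 200 genes, 300 true sites) keeps roughly 1.5 sites per gene
so gene-level binding is not saturated and condition loss is visible in
unique-bound-gene counts, as in the real data where severe disease binds
fewer unique RNAs.

They do *not* emulate realistic transcript sequence content, read-level
noise, alignment artefacts, peak-caller idiosyncrasies, or biological
covariance between neighbouring sites.  Passing tests therefore establish
that the computations are correct under the stated model, not that the
model captures every property of real CLIP-seq data.

Problem sizes in the tests are chosen to make sampling error small
relative to the asserted tolerances: 10,000 pairs for parameter recovery
(±0.05 on π₁, ±0.10 on ρ₁ over 20 seeds), 5,000 for null calibration,
2,000 sites for region-bias recovery (±0.03), depth 2,000 × 5 samples for
PSI (±0.03), 100 seeds for motif-null calibration, 20 seeds for the
condition trend.

## Known limitations

* The IDR fit requires ≥ 50 matched pairs and a score column; it does
  not handle censored/tied-at-threshold score mass specially.
* Greedy score-descending peak matching is deterministic and fast but
  not guaranteed optimal; the test suite quantifies the gap against an
  exhaustive maximum-weight matching oracle (optimal in ≥ 95% of random
  instances, never better than the optimum).
* `venn_partition()` is exact for any number of conditions but its
  region labels grow combinatorially; it is intended for the 2–4
  condition scale of the study design.
* The pipeline's `repro` stage is the slow path (four mixture fits per
  replicate pair); it can be toggled off when only footprints and
  comparisons are needed.
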
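#' Percent spliced-in (PSI) from junction counts
#'
#' Length-normalised inclusion fraction of an alternative exon:
#' `PSI = (I / l_I) / (I / l_I + S / l_S)` with inclusion count `I`,
#' skipping count `S` and their effective lengths.  Accepts a junction
#' table (as from [simulate_assay_tables()]) and returns it with a `psi`
#' column.
#'
#' @param junctions Data frame with columns `inclusion`, `skipping`,
#'   `inclusion_length`, `skipping_length`.
#' @return The input as a tibble with an added `psi` column in `[0, 1]`.
#' @examples
#' psi(tibble::tibble(inclusion = 80, skipping = 20,
#'                    inclusion_length = 100, skipping_length = 50))$psi
#' @export
psi <- function(junctions) {
  junctions <- as_tibble(junctions)
  need <- c("inclusion", "skipping", "inclusion_length", "skipping_length")
  miss <- setdiff(need, names(junctions))
  if (length(miss))
    abort(paste0("missing junction columns: ", paste(miss, collapse = ", ")))
  with(junctions, {
    if (any(inclusion < 0) || any(skipping < 0))
      abort("counts must be non-negative")
    if (any(inclusion + skipping == 0))
      abort("inclusion + skipping must be positive for quantification")
    if (any(inclusion_length <= 0) || any(skipping_length <= 0))
      abort("effective lengths must be positive")
  })
  mutate(junctions, psi = (.data$inclusion / .data$inclusion_length) /
           (.data$inclusion / .data$inclusion_length +
              .data$skipping / .data$skipping_length))
}

#' Between-group PSI difference
#'
#' `delta_psi = mean PSI(control) - mean PSI(case)`: positive values mean
#' higher inclusion in the control group.
#'
#' @param junctions Junction table with a `group` column.
#' @param control,case Group labels.
#' @return One-row tibble with `psi_control`, `psi_case`, `delta_psi`.
#' @export
delta_psi <- function(junctions, control = "control", case = "case") {
  q <- psi(junctions)
  if (!"group" %in% names(q)) abort("junction table needs a `group` column")
  m <- function(g) {
    v <- q$psi[q$group == g]
    if (!length(v)) abort(paste0("no samples in group ", g))
    mean(v)
  }
  tibble(psi_control = m(control), psi_case = m(case),
         delta_psi = m(control) - m(case))
}

#' Relative inclusion from a three-primer PCR assay
#'
#' The three-primer assay yields an inclusion product A and a skipping
#' product B; the relative inclusion of the alternative exon in a lane is
#' `A / (A + B)`.
#'
#' @param band_a,band_b Non-negative band intensities (vectorised).
#' @return Numeric inclusion fraction(s) in `[0, 1]`.
#' @export
inclusion_ratio <- function(band_a, band_b) {
  if (any(band_a < 0) || any(band_b < 0)) abort("intensities must be >= 0")
  if (any(band_a + band_b == 0)) abort("A + B must be positive")
  band_a / (band_a + band_b)
}

#' Secondary-isoform fraction from a restriction digest
#'
#' When only the secondary isoform carries the restriction site, digestion
#' leaves the primary isoform as a single uncut band and cleaves the
#' secondary isoform into a doublet; its fraction is
#' `(cut_1 + cut_2) / (uncut + cut_1 + cut_2)`.
#'
#' @param uncut,cut_1,cut_2 Non-negative band intensities (vectorised).
#' @return Numeric secondary-isoform fraction(s).
#' @export
digest_isoform_fraction <- function(uncut, cut_1, cut_2) {
  if (any(uncut < 0) || any(cut_1 < 0) || any(cut_2 < 0))
    abort("intensities must be >= 0")
  total <- uncut + cut_1 + cut_2
  if (any(total == 0)) abort("total band intensity must be positive")
  (cut_1 + cut_2) / total
}

#' Fold change by delta-delta-Ct
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; `ddCt` subtracts the
#' arithmetic mean `dCt` of the calibrator group; the fold change is
#' `2^(-ddCt)`.  The calibrator group's fold changes have geometric mean 1
#' by construction.
#'
#' @param ct Data frame with columns `sample_id`, `group`, `ct_target`,
#'   `ct_reference`.
#' @param calibrator Calibrator group label.
#' @return The input as a tibble with added `dct`, `ddct`, `fold_change`.
#' @export
ddct_fold_change <- function(ct, calibrator = "control") {
  ct <- as_tibble(ct)
  need <- c("group", "ct_target", "ct_reference")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    abort(paste0("missing Ct columns: ", paste(miss, collapse = ", ")))
  if (anyNA(ct$ct_target) || anyNA(ct$ct_reference))
    abort("missing Ct values")
  if (!any(ct$group == calibrator))
    abort(paste0("calibrator group not present: ", calibrator))
  ct <- mutate(ct, dct = .data$ct_target - .data$ct_reference)
  cal_mean <- mean(ct$dct[ct$group == calibrator])
  mutate(ct, ddct = .data$dct - cal_mean,
         fold_change = 2^(-.data$ddct))
}

#' Neurite length summary as percent of wild type
#'
#' Per image, the average neurite length is the total traced length
#' divided by the nucleus count (images with zero nuclei are excluded and
#' counted); per replicate and group these are averaged; each group is
#' then expressed as a percentage of the matched wild-type replicate.
#'
#' @param measurements Data frame with columns `replicate`, `group`,
#'   `total_length_um`, `n_nuclei` (one row per image).
#' @param wt_group Label of the wild-type group used as the 100% anchor.
#' @return Tibble with `replicate`, `group`, `mean_length_um`,
#'   `percent_of_wt`; the attribute `n_excluded_images` counts zero-nuclei
#'   images dropped.
#' @export
neurite_summary <- function(measurements, wt_group = "WT") {
  m <- as_tibble(measurements)
  need <- c("replicate", "group", "total_length_um", "n_nuclei")
  miss <- setdiff(need, names(m))
  if (length(miss))
    abort(paste0("missing neurite columns: ", paste(miss, collapse = ", ")))
  bad <- m$n_nuclei < 1
  if (any(bad))
    warn(paste0(sum(bad), " image(s) with zero nuclei excluded"))
  m <- m[!bad, , drop = FALSE]
  if (!any(m$group == wt_group))
    abort(paste0("wild-type group not present: ", wt_group))
  per_rep <- m %>%
    mutate(avg_length = .data$total_length_um / .data$n_nuclei) %>%
    group_by(.data$replicate, .data$group) %>%
    summarise(mean_length_um = mean(.data$avg_length), .groups = "drop")
  wt <- per_rep %>%
    filter(.data$group == wt_group) %>%
    select("replicate", wt_length = "mean_length_um")
  out <- per_rep %>%
    left_join(wt, by = "replicate") %>%
    mutate(percent_of_wt = 100 * .data$mean_length_um / .data$wt_length) %>%
    select(-"wt_length")
  attr(out, "n_excluded_images") <- sum(bad)
  out
}

# exact two-sided Mann-Whitney p by full enumeration of the
# choose(n1 + n2, n1) group assignments of the observed values
mann_whitney_exact <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  if (n1 + n2 > 20)
    abort("exact Mann-Whitney enumeration is limited to combined n <= 20")
  vals <- c(a, b)
  r <- rank(vals)  # midranks on ties
  u_from_idx <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_from_idx(seq_len(n1))
  idx_all <- combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[idx_all], nrow = n1)) - n1 * (n1 + 1) / 2
  mid <- n1 * n2 / 2
  # two-sided: assignments at least as far from the null mean as observed
  p <- mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-9)
  list(statistic = u_obs, p_value = p, n_perm = ncol(idx_all))
}

#' Group comparison tests used for assay readouts
#'
#' Small-sample tests matching the figure statistics: the exact two-sided
#' Mann-Whitney U test by full enumeration of all group assignments
#' (midranks on ties; combined n capped at 20), and one- or two-tailed t
#' tests (Welch by default, pooled-variance optionally).
#'
#' @param values_a,values_b Numeric vectors for the two groups.
#' @param test `"mann_whitney_exact"`, `"t_one_tailed"` or
#'   `"t_two_tailed"`.
#' @param alternative For the one-tailed t test: is the mean of group A
#'   `"greater"` or `"less"` than group B's?
#' @param var_equal Pooled-variance t test instead of Welch.
#' @return One-row tibble with `method`, `statistic`, `p_value`, `n_a`,
#'   `n_b`.
#' @examples
#' group_test(c(1, 2, 3), c(4, 5, 6, 7, 8))$p_value  # 2/56 = 0.0357
#' @export
group_test <- function(values_a, values_b,
                       test = c("mann_whitney_exact", "t_one_tailed",
                                "t_two_tailed"),
                       alternative = c("greater", "less"),
                       var_equal = FALSE) {
  test <- match.arg(test)
  if (!length(values_a) || !length(values_b))
    abort("both groups must be non-empty")
  if (test == "mann_whitney_exact") {
    res <- mann_whitney_exact(values_a, values_b)
    return(tibble(method = "mann_whitney_exact",
                  statistic = res$statistic, p_value = res$p_value,
                  n_a = length(values_a), n_b = length(values_b)))
  }
  alt <- if (test == "t_two_tailed") "two.sided" else match.arg(alternative)
  tt <- t.test(values_a, values_b, alternative = alt,
               var.equal = var_equal)
  tibble(method = test, statistic = unname(tt$statistic),
         p_value = tt$p.value,
         n_a = length(values_a), n_b = length(values_b))
}
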
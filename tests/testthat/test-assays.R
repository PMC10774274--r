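jt <- function(I, S, lI = 1, lS = 1, group = "control") {
  tibble::tibble(inclusion = I, skipping = S, inclusion_length = lI,
                 skipping_length = lS, group = group)
}

test_that("psi follows the length-normalised formula", {
  expect_equal(psi(jt(80, 20))$psi, 0.8)
  expect_equal(psi(jt(0, 20))$psi, 0)
  expect_equal(psi(jt(80, 0))$psi, 1)
  # direct arithmetic: (80/100) / (80/100 + 20/50) = 0.6667
  expect_equal(psi(jt(80, 20, lI = 100, lS = 50))$psi, 0.8 / 1.2,
               tolerance = 1e-12)
  # scale invariance and monotonicity in inclusion
  expect_equal(psi(jt(8, 2))$psi, psi(jt(800, 200))$psi)
  p <- psi(jt(c(10, 20, 30), c(50, 50, 50)))$psi
  expect_true(all(diff(p) > 0))
  expect_error(psi(jt(0, 0)), "positive")
})

test_that("delta_psi uses the control-minus-case sign convention", {
  d <- delta_psi(dplyr::bind_rows(jt(90, 10, group = "control"),
                                  jt(60, 40, group = "case")))
  expect_equal(d$delta_psi, 0.3)
  expect_gt(d$delta_psi, 0)  # higher inclusion in controls is positive
  same <- delta_psi(dplyr::bind_rows(jt(50, 50, group = "control"),
                                     jt(50, 50, group = "case")))
  expect_equal(same$delta_psi, 0)
  expect_error(delta_psi(jt(1, 1, group = "control")), "no samples")
})

test_that("simulated junction tables recover the planted group difference", {
  sc <- clip_scenario(seed = 13, junction_depth = 2000L,
                      psi_by_group = c(control = 0.7, case = 0.4),
                      n_per_group = 5L)
  d <- delta_psi(simulate_assay_tables(sc)$junctions)
  expect_lt(abs(d$psi_control - 0.7), 0.03)
  expect_lt(abs(d$psi_case - 0.4), 0.03)
  expect_lt(abs(d$delta_psi - 0.3), 0.03)
})

test_that("inclusion ratio and digest fraction are exact band arithmetic", {
  expect_equal(inclusion_ratio(5, 5), 0.5)
  expect_equal(inclusion_ratio(5, 0), 1)
  expect_equal(inclusion_ratio(30, 70), 0.3)
  expect_equal(inclusion_ratio(30, 70) + 70 / (30 + 70), 1)
  expect_error(inclusion_ratio(0, 0), "positive")

  expect_equal(digest_isoform_fraction(30, 35, 35), 0.7)
  expect_equal(digest_isoform_fraction(10, 0, 0), 0)
  withr::with_seed(3, {
    for (i in 1:20) {
      v <- runif(3, 0.01, 100)
      expect_equal(digest_isoform_fraction(v[1], v[2], v[3]),
                   (v[2] + v[3]) / sum(v))
    }
  })
  expect_error(digest_isoform_fraction(0, 0, 0), "positive")
})

test_that("ddct recovers planted fold changes exactly", {
  # construct Ct values from known folds: dCt = base - log2(fold)
  planted <- c(1, 1, 1, 2, 2, 0.25, 0.25)
  groups <- c("control", "control", "control", "up", "up", "down", "down")
  ct <- tibble::tibble(
    sample_id = paste0("s", seq_along(planted)), group = groups,
    ct_reference = 15, ct_target = 15 + 5 - log2(planted))
  out <- ddct_fold_change(ct, calibrator = "control")
  expect_equal(out$fold_change, planted)
  # calibrator geometric mean is 1 by construction
  cal <- out$fold_change[out$group == "control"]
  expect_equal(exp(mean(log(cal))), 1)
  # one cycle below the calibrator mean doubles expression
  one_less <- ddct_fold_change(
    tibble::tibble(sample_id = c("a", "b"), group = c("control", "x"),
                   ct_reference = 10, ct_target = c(16, 15)))
  expect_equal(one_less$fold_change[2], 2)
  expect_error(ddct_fold_change(ct, calibrator = "missing"), "calibrator")
  ct$ct_target[1] <- NA
  expect_error(ddct_fold_change(ct), "missing Ct")
})

test_that("geometric-mean-1 calibrator invariant holds with noisy Ct", {
  sc <- clip_scenario(seed = 21)
  out <- ddct_fold_change(simulate_assay_tables(sc)$ct,
                          calibrator = "control")
  cal <- out$fold_change[out$group == "control"]
  expect_equal(exp(mean(log(cal))), 1, tolerance = 1e-12)
})

test_that("neurite summary divides by nuclei, normalises to WT, drops bad images", {
  m <- tibble::tibble(
    replicate = rep(c("r1", "r2"), each = 4),
    group = rep(c("WT", "WT", "F263S", "F263S"), 2),
    total_length_um = c(1000, 1200, 500, 700, 800, 800, 900, 700),
    n_nuclei = c(10, 12, 10, 10, 8, 8, 10, 10))
  out <- neurite_summary(m)
  expect_equal(out$percent_of_wt[out$group == "WT"], c(100, 100))
  # r1: WT mean = (100 + 100)/2 = 100; mutant = (50 + 70)/2 = 60 -> 60%
  expect_equal(out$percent_of_wt[out$group == "F263S" &
                                   out$replicate == "r1"], 60)
  # r2: WT 100, mutant (90 + 70)/2 = 80 -> 80%
  expect_equal(out$percent_of_wt[out$group == "F263S" &
                                   out$replicate == "r2"], 80)
  m$n_nuclei[3] <- 0
  expect_warning(out2 <- neurite_summary(m), "zero nuclei")
  expect_identical(attr(out2, "n_excluded_images"), 1L)
  expect_equal(out2$percent_of_wt[out2$group == "F263S" &
                                    out2$replicate == "r1"], 70)
})

test_that("exact Mann-Whitney reproduces the complete-separation p and symmetries", {
  res <- group_test(c(1, 2, 3), c(4, 5, 6, 7, 8))
  expect_equal(res$p_value, 2 / 56, tolerance = 1e-12)
  expect_equal(res$p_value, 0.0357, tolerance = 1e-3)
  # symmetric under group swap and order reversal of values
  swap <- group_test(c(4, 5, 6, 7, 8), c(1, 2, 3))
  expect_equal(swap$p_value, res$p_value)
  neg <- group_test(-c(1, 2, 3), -c(4, 5, 6, 7, 8))
  expect_equal(neg$p_value, res$p_value)
  # identical groups sit at the null midpoint with p = 1
  bal <- group_test(c(1, 4), c(2, 3))
  expect_equal(bal$statistic, 2)  # n1 n2 / 2
  expect_equal(bal$p_value, 1)
  expect_error(group_test(numeric(0), 1:3), "non-empty")
  expect_error(group_test(1:11, 1:10), "n <= 20")
})

test_that("exact Mann-Whitney matches enumeration via wilcox.test for n1, n2 <= 6", {
  withr::with_seed(55, {
    for (case in 1:30) {
      n1 <- sample(1:6, 1)
      n2 <- sample(1:6, 1)
      # distinct values so the reference exact path applies
      v <- sample(seq_len(100), n1 + n2)
      a <- v[seq_len(n1)]
      b <- v[-seq_len(n1)]
      got <- group_test(a, b)$p_value
      want <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))$p.value
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
})

test_that("one- and two-tailed t tests delegate with the right alternative", {
  a <- c(5.1, 5.4, 5.0)
  b <- c(4.2, 4.0, 4.4)
  one <- group_test(a, b, test = "t_one_tailed", alternative = "greater")
  two <- group_test(a, b, test = "t_two_tailed")
  expect_lt(one$p_value, two$p_value)
  expect_equal(two$p_value,
               t.test(a, b, alternative = "two.sided")$p.value)
  pooled <- group_test(a, b, test = "t_one_tailed", alternative = "greater",
                       var_equal = TRUE)
  expect_equal(pooled$p_value,
               t.test(a, b, alternative = "greater",
                      var.equal = TRUE)$p.value)
})
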
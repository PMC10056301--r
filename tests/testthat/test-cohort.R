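test_that("normality screen is calibrated and rejects bimodal samples", {
  ok <- vapply(1:100, function(s) {
    withr::with_seed(s, normality_screen(rnorm(22))$p_value > 0.05)
  }, logical(1))
  expect_gte(mean(ok), 0.90)
  bimodal <- withr::with_seed(3, c(rnorm(11, -4, 0.3), rnorm(11, 4, 0.3)))
  expect_lt(normality_screen(bimodal)$p_value, 0.05)
  expect_error(normality_screen(rep(1, 10)), "variance")
  expect_error(normality_screen(rnorm(2)), "3 <= n")
})

test_that("paired comparison reproduces the textbook t statistic", {
  d <- withr::with_seed(8, 1 + rnorm(12, 0, 0.4))
  b <- withr::with_seed(9, rnorm(12, 10, 1))
  a <- b + d
  row <- paired_compare(a, b)
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(row$test_used, "paired t")
  expect_equal(row$statistic, t_hand, tolerance = 1e-10)
  ci_hand <- mean(d) + c(-1, 1) * qt(0.975, 11) * sd(d) / sqrt(12)
  expect_equal(c(row$diff_ci_lo, row$diff_ci_hi), ci_hand, tolerance = 1e-10)
})

test_that("paired comparison edge cases and antisymmetry", {
  x <- withr::with_seed(2, rnorm(10, 5))
  same <- paired_compare(x, x)
  expect_equal(c(same$diff_ci_lo, same$diff_ci_hi), c(0, 0))
  expect_equal(same$stars, "")
  expect_equal(same$p_value, 1)

  y <- withr::with_seed(3, x + rnorm(10, 0.5, 0.2))
  ab <- paired_compare(x, y)
  ba <- paired_compare(y, x)
  expect_equal(ab$diff_ci_lo, -ba$diff_ci_hi, tolerance = 1e-12)
  expect_equal(ab$diff_ci_hi, -ba$diff_ci_lo, tolerance = 1e-12)
  expect_equal(ab$statistic, -ba$statistic, tolerance = 1e-12)
  expect_error(paired_compare(x, y[-1]), "paired")
})

test_that("non-normal differences switch to the signed-rank test", {
  b <- withr::with_seed(4, rnorm(20, 10))
  skew <- withr::with_seed(5, rexp(20)^3)
  a <- b + skew
  expect_equal(paired_compare(a, b)$test_used, "wilcoxon signed-rank")
})

test_that("condition comparison recovers the sign of injected offsets", {
  # offsets well above 3 SE at n = 22 must come out starred with the
  # right sign; components with no offset mostly unstarred
  delta <- c(NAA = 0.8, Ins = -0.6)
  tab <- simulate_cohort_table(n_subjects = 22, crlb_frac = 0.05,
                               delta_mM = delta, seed = 77)
  cmp <- compare_conditions(tab, conditions = c("in_house", "simulated"))
  naa <- cmp[cmp$component == "NAA", ]
  ins <- cmp[cmp$component == "Ins", ]
  # condition b = simulated carries +delta, so a - b has sign -delta
  expect_lt(naa$diff_ci_hi, 0)
  expect_gt(ins$diff_ci_lo, 0)
  expect_true(naa$stars != "")
  expect_true(ins$stars != "")
})

test_that("condition swap negates CIs and statistics exactly", {
  tab <- simulate_cohort_table(n_subjects = 12, seed = 15)
  fwd <- compare_conditions(tab, conditions = c("in_house", "simulated"))
  rev <- compare_conditions(tab, conditions = c("simulated", "in_house"))
  expect_equal(fwd$diff_ci_lo, -rev$diff_ci_hi, tolerance = 1e-12)
  expect_equal(fwd$statistic, -rev$statistic, tolerance = 1e-12)
})

test_that("correlation matrix is symmetric, unit-diagonal and masked", {
  tab <- simulate_cohort_table(n_subjects = 22, seed = 21)
  M <- correlation_matrix(tab, condition = "in_house", alpha = 0.1)
  expect_true(isSymmetric(M))
  expect_equal(unname(diag(M)), rep(1, ncol(M)))

  # constructed strong negative pair is found and unmasked
  x <- withr::with_seed(31, rnorm(22, 10))
  pair <- tibble::tibble(
    subject = rep(sprintf("S%02d", 1:22), 2),
    component = rep(c("A", "B"), each = 22),
    condition = "c1",
    conc_mM = c(x, withr::with_seed(32, 20 - x + rnorm(22, 0, 0.05))))
  Mp <- correlation_matrix(pair, condition = "c1")
  expect_lt(Mp["A", "B"], -0.99)
})

test_that("independent pairs are mostly masked at alpha 0.1", {
  masked <- vapply(1:200, function(s) {
    d <- withr::with_seed(s, tibble::tibble(
      subject = rep(sprintf("S%02d", 1:22), 2),
      component = rep(c("A", "B"), each = 22),
      condition = "c1", conc_mM = rnorm(44)))
    is.na(correlation_matrix(d, condition = "c1", alpha = 0.1)["A", "B"])
  }, logical(1))
  expect_gte(mean(masked), 0.85)
})

test_that("masking is monotone in alpha", {
  tab <- simulate_cohort_table(n_subjects = 22, seed = 41)
  M05 <- correlation_matrix(tab, condition = "in_house", alpha = 0.05)
  M10 <- correlation_matrix(tab, condition = "in_house", alpha = 0.1)
  # everything visible at 0.05 stays visible at 0.1
  expect_true(all(is.na(M05) | !is.na(M10)))
})

test_that("zero-variance components are masked with a warning", {
  tab <- tibble::tibble(
    subject = rep(sprintf("S%02d", 1:10), 2),
    component = rep(c("A", "B"), each = 10),
    condition = "c1",
    conc_mM = c(rep(1, 10), withr::with_seed(1, rnorm(10))))
  expect_warning(M <- correlation_matrix(tab, condition = "c1"), "Zero-variance")
  expect_true(all(is.na(M["A", ])))
})

test_that("CV is the sample SD over the mean, in percent", {
  expect_equal(coefficient_of_variation(c(1, 1, 1)), 0)
  expect_equal(coefficient_of_variation(c(0.9, 1.0, 1.1)), 10,
               tolerance = 1e-12)
  x <- withr::with_seed(6, rnorm(30, 10, 2))
  expect_equal(coefficient_of_variation(5 * x), coefficient_of_variation(x),
               tolerance = 1e-12)
  expect_error(coefficient_of_variation(c(-2, -1)), "positive mean")
})

test_that("CV-vs-CRLB classification applies the dominance rule and bands", {
  tab <- tibble::tibble(
    subject = rep(sprintf("S%02d", 1:10), 3),
    component = rep(c("hiCV", "tie", "noisy"), each = 10),
    condition = "c1",
    conc_mM = c(withr::with_seed(1, rnorm(10, 10, 2)),   # CV ~ 20%
                rep(c(9, 11), 5),                        # CV fixed below
                withr::with_seed(2, rnorm(10, 10, 1))),
    crlb_rel = rep(c(10, NA, 40), each = 10))
  tab$crlb_rel[tab$component == "tie"] <-
    coefficient_of_variation(tab$conc_mM[tab$component == "tie"])
  out <- cv_vs_crlb(tab)
  expect_equal(out$dominance[out$component == "hiCV"], "CV-dominant")
  expect_equal(out$crlb_band[out$component == "hiCV"], "<15%")
  # exact tie counts as CRLB-dominant
  expect_equal(out$dominance[out$component == "tie"], "CRLB-dominant")
  expect_equal(out$crlb_band[out$component == "noisy"], ">=35%")
})

test_that("injected between-subject variability is seen as CV-dominant", {
  hits <- vapply(1:50, function(s) {
    tab <- simulate_cohort_table(
      n_subjects = 22,
      concentration_table = tibble::tibble(component = "NAA", mean_mM = 8.5,
                                           between_sd_mM = 0.9),
      crlb_frac = 0.053, seed = s)  # CRLB ~ 0.45 mM, between-SD 2x that
    out <- cv_vs_crlb(tab[tab$condition == "in_house", ])
    out$dominance == "CV-dominant"
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})
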
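test_that("model_predict obeys the linear-combination structure", {
  g <- test_grid
  b <- three_component_basis()
  cfg <- fit_config()
  idx <- which(ppm_axis(g) >= cfg$fit_range[1] & ppm_axis(g) <= cfg$fit_range[2])

  zero <- model_predict(list(amplitudes = c(NAA = 0, Cr = 0, Ins = 0),
                             spline_coefficients = numeric(0)), b, cfg)
  expect_equal(zero, numeric(length(idx)))

  one <- model_predict(list(amplitudes = c(NAA = 1, Cr = 0, Ins = 0),
                            spline_coefficients = numeric(0)), b, cfg)
  expect_equal(one, Re(b$components$NAA$spectrum$signal)[idx])

  expect_error(model_predict(list(amplitudes = c(NAA = 1),
                                  spline_coefficients = numeric(0)), b, cfg),
               "every basis component")
})

test_that("Lorentzian broadening lowers peaks but preserves area", {
  g <- test_grid
  b <- single_line_basis("NAA", linewidth = 4)
  # fit range spanning (almost) the whole grid, so the numeric integral
  # sees the full line including tails
  ppm <- ppm_axis(g)
  cfg <- fit_config(fit_range = c(min(ppm) + 0.01, max(ppm) - 0.01),
                    max_shift = 0)
  p0 <- list(amplitudes = c(NAA = 1), spline_coefficients = numeric(0),
             broadening = 0)
  p1 <- modifyList(p0, list(broadening = 3))
  y0 <- model_predict(p0, b, cfg)
  y1 <- model_predict(p1, b, cfg)
  expect_lt(max(y1), max(y0))
  expect_equal(sum(y1) / sum(y0), 1, tolerance = 1e-4)
})

test_that("noiseless single-component spectrum is recovered exactly", {
  g <- test_grid
  b <- single_line_basis("NAA")
  a_true <- 7.3
  sp <- make_subject_spectrum(ground_truth(c(NAA = a_true)), b, g)$spectrum
  fit <- fit_spectrum(sp, b)
  expect_equal(unname(fit$amplitudes[["NAA"]]), a_true,
               tolerance = 0.001)
  expect_lt(sqrt(mean(fit$residual^2)), 1e-8 * max(Re(sp$signal)))
})

test_that("zero spectrum fits to zero amplitudes and baseline", {
  g <- test_grid
  b <- three_component_basis()
  fit <- fit_spectrum(mrs_spectrum(complex(g$n_points), g), b)
  expect_true(all(fit$amplitudes == 0))
  expect_lt(max(abs(fit$baseline)), 1e-10)
})

test_that("fit scales linearly with the input amplitude", {
  g <- test_grid
  b <- three_component_basis()
  tr <- ground_truth(c(NAA = 8, Cr = 5, Ins = 4), noise_sd = 0.3, seed = 31)
  sp <- make_subject_spectrum(tr, b, g)$spectrum
  f1 <- fit_spectrum(sp, b, ls_config())
  f3 <- fit_spectrum(mrs_spectrum(sp$signal * 3, g), b, ls_config())
  expect_equal(unname(f3$amplitudes), unname(3 * f1$amplitudes),
               tolerance = 1e-6)
})

test_that("residual is orthogonal to active basis directions", {
  g <- test_grid
  b <- three_component_basis()
  tr <- ground_truth(c(NAA = 8, Cr = 5, Ins = 4), noise_sd = 0.5, seed = 7)
  sp <- make_subject_spectrum(tr, b, g)$spectrum
  fit <- fit_spectrum(sp, b, ls_config())
  # numeric directional derivative of the RSS along each active amplitude
  base <- list(amplitudes = fit$amplitudes,
               spline_coefficients = fit$spline_coefficients,
               phase0 = fit$phase0, broadening = fit$global_broadening)
  rss <- function(p) sum((fit$y - model_predict(p, b, fit$config))^2)
  eps <- 1e-6
  for (m in names(fit$amplitudes)) {
    up <- base; up$amplitudes[m] <- up$amplitudes[m] + eps
    dn <- base; dn$amplitudes[m] <- dn$amplitudes[m] - eps
    deriv <- (rss(up) - rss(dn)) / (2 * eps)
    expect_lt(abs(deriv), 1e-4 * rss(base))
  }
})

test_that("alpha_B monotonically smooths the baseline", {
  g <- test_grid
  b <- single_line_basis("NAA")
  # wiggly additive baseline to give the spline something to chase
  nb <- n_baseline_coefficients()
  tr <- ground_truth(c(NAA = 6),
                     baseline_coefficients = sin(seq_len(nb)) * 2,
                     noise_sd = 0.3, seed = 13)
  sp <- make_subject_spectrum(tr, b, g)$spectrum
  curv <- vapply(c(0.01, 1, 100, 1e4, 1e6), function(a) {
    f <- fit_spectrum(sp, b, fit_config(alpha_B = a, max_shift = 0,
                                        max_broadening = 0, n_starts = 1))
    sum(diff(f$spline_coefficients, differences = 2)^2)
  }, numeric(1))
  expect_true(all(diff(curv) <= 1e-9 + 1e-6 * curv[-length(curv)]))
})

test_that("CRLB follows the Fisher-information closed form", {
  g <- test_grid
  b <- single_line_basis("NAA")
  sp <- make_subject_spectrum(ground_truth(c(NAA = 5)), b, g)$spectrum
  cfg <- ls_config(baseline_knot_spacing = NULL)
  fit <- fit_spectrum(sp, b, cfg)
  # zero noise gives zero bounds
  expect_equal(unname(compute_crlb(fit, 0)$crlb_abs), 0)
  # single orthogonal component: crlb = noise_sd / ||B||
  idx <- fit$idx
  Bnorm <- sqrt(sum(Re(b$components$NAA$spectrum$signal[idx])^2))
  expect_equal(unname(compute_crlb(fit, 0.5)$crlb_abs), 0.5 / Bnorm,
               tolerance = 1e-9)
})

test_that("combined CRLBs use the member covariance block", {
  # constructed fit object with controlled covariance algebra
  mk_fit <- function(cov_unit, conc) {
    structure(list(amplitudes = conc, concentrations = conc,
                   covariance_unit = cov_unit, noise_sd = 1,
                   scale_mM = setNames(rep(1, length(conc)), names(conc))),
              class = "mrs_fit")
  }
  basis_combo <- list(combinations = list(tNA = c("NAA", "NAAG")))
  conc <- c(NAA = 8, NAAG = 1)

  # independent members: quadrature sum
  ind <- diag(c(0.3^2, 0.4^2)); dimnames(ind) <- list(names(conc), names(conc))
  out <- combine_metabolites(mk_fit(ind, conc), basis_combo)
  expect_equal(out$combinations$conc_mM, 9)  # concentrations additive
  expect_equal(out$combinations$crlb_mM, sqrt(0.3^2 + 0.4^2))

  # perfectly anti-correlated members: sum better determined than either
  anti <- matrix(c(0.3^2, -0.3 * 0.4, -0.3 * 0.4, 0.4^2), 2,
                 dimnames = list(names(conc), names(conc)))
  out2 <- combine_metabolites(mk_fit(anti, conc), basis_combo)
  expect_equal(out2$combinations$crlb_mM, abs(0.3 - 0.4), tolerance = 1e-12)
  expect_lt(out2$combinations$crlb_mM, 0.3)

  expect_error(
    combine_metabolites(mk_fit(ind, conc),
                        list(combinations = list(tCr = c("Cr", "PCr")))),
    "missing member")
})

test_that("cohort-level parameter recovery: singles and sums", {
  g <- test_grid
  b <- brain_basis(g, include_mm = FALSE)
  quant <- quant_config()
  water <- ideal_water_reference(quant, grid = g)
  # noise for SNR ~ 20 given NAA peak height at typical concentrations
  cfg <- fast_config()
  n_spec <- 12
  co <- simulate_cohort(n_spec, b, noise_sd = 0.35, quant = quant,
                        phase_sd = 0.05, seed = 101)
  singles <- c("NAA", "Ins", "Glu")
  combos <- c("tNA", "tCr", "tCho", "Glx")
  err_single <- matrix(NA_real_, n_spec, length(singles),
                       dimnames = list(NULL, singles))
  combo_ok <- logical(0)
  for (i in seq_len(n_spec)) {
    fit <- fit_spectrum(co[[i]]$spectrum, b, cfg)
    fit <- quantify_fit(fit, b, co[[i]]$water, quant)
    fit <- combine_metabolites(fit, b)
    tr <- co[[i]]$truth$concentrations
    err_single[i, ] <- abs(fit$concentrations[singles] / tr[singles] - 1)
    for (cb in combos) {
      members <- default_combinations()[[cb]]
      rel_m <- abs(fit$concentrations[members] / tr[members] - 1)
      row <- fit$combinations[fit$combinations$component == cb, ]
      rel_c <- abs(row$conc_mM / sum(tr[members]) - 1)
      combo_ok <- c(combo_ok, rel_c <= max(rel_m) + 1e-9)
    }
  }
  expect_lt(median(err_single), 0.10)
  expect_true(all(combo_ok))
})
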
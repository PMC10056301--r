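test_that("zero-order phasing inverts an applied rotation", {
  g <- test_grid
  # single absorption line centered in the phasing window: the complex sum
  # over a symmetric window has zero argument, so the round trip is exact
  b <- make_basis_component(
    data.frame(center_ppm = 3.0, relative_amplitude = 2), 3, g)
  s0 <- b$spectrum
  rot <- mrs_spectrum(s0$signal * exp(1i * pi / 6), g)
  ph <- zero_order_phase(rot)
  expect_equal(ph$phase0 * 180 / pi, -30, tolerance = 0.5)
  # already-phased input
  expect_equal(zero_order_phase(s0)$phase0, 0, tolerance = 1e-2)
  expect_error(zero_order_phase(mrs_spectrum(complex(g$n_points), g)),
               "all-zero")
})

test_that("closed-form phase matches a grid search over 3600 candidates", {
  g <- test_grid
  b <- make_basis_component(
    data.frame(center_ppm = c(2.0, 3.4), relative_amplitude = c(3, 2)), 4, g)
  rot <- mrs_spectrum(b$spectrum$signal * exp(1i * 1.1), g)
  idx <- which(ppm_axis(g) >= 1.8 & ppm_axis(g) <= 4.2)
  phis <- seq(-pi, pi, length.out = 3600)
  scores <- vapply(phis, function(p) {
    sum(Re(rot$signal[idx] * exp(1i * p)))
  }, numeric(1))
  oracle <- phis[which.max(scores)]
  got <- zero_order_phase(rot)$phase0
  expect_equal(got, oracle, tolerance = 2 * pi / 3600 + 1e-9)
  # pi rotation (inverted spectrum) is the worst case, never returned
  # for absorption-mode input
  expect_lt(abs(zero_order_phase(b$spectrum)$phase0), pi / 2)
})

test_that("water FWHM fit recovers the generating linewidth", {
  g <- test_grid
  expect_equal(fit_water_fwhm(make_water_reference(100, 5, g)), 5,
               tolerance = 0.01)
  # boundary semantics: 8 Hz passes the filter (excluded only above 8)
  f8 <- fit_water_fwhm(make_water_reference(100, 8, g))
  expect_equal(f8, 8, tolerance = 0.01)
  expect_true(f8 <= 8 * 1.001)
  # doubling the linewidth doubles the estimate
  f10 <- fit_water_fwhm(make_water_reference(100, 10, g))
  expect_equal(f10 / fit_water_fwhm(make_water_reference(100, 5, g)), 2,
               tolerance = 0.02)
})

test_that("water FWHM recovery holds across 1-12 Hz", {
  g <- test_grid
  for (w in c(1, 2, 4, 6, 8, 10, 12)) {
    expect_equal(fit_water_fwhm(make_water_reference(80, w, g)), w,
                 tolerance = 0.01 * w)
  }
})

test_that("SNR estimator matches construction and is scale invariant", {
  g <- test_grid
  b <- single_line_basis("NAA")
  # peak height: conc * protons * 2/(pi*w); choose conc for height 100
  h_unit <- max(Re(b$components$NAA$spectrum$signal))
  conc <- 100 / h_unit
  tr <- ground_truth(setNames(conc, "NAA"), noise_sd = 10, seed = 21)
  sp <- make_subject_spectrum(tr, b, g)$spectrum
  snr <- estimate_snr(sp)
  expect_equal(snr, 10, tolerance = 0.2 * 10)
  sp2 <- mrs_spectrum(sp$signal * 7.3, g)
  expect_equal(estimate_snr(sp2), snr, tolerance = 1e-9)
  # exactly noiseless input (flat noise window) has undefined SNR
  spike <- complex(g$n_points)
  spike[which.min(abs(ppm_axis(g) - 2))] <- 100 + 0i
  expect_error(estimate_snr(mrs_spectrum(spike, g)), "undefined|zero")
})

test_that("suppression efficiency is a simple height ratio", {
  g <- test_grid
  pre <- make_water_reference(200, 6, g)
  expect_equal(suppression_efficiency(pre, pre), 1.0)
  post <- mrs_spectrum(pre$signal * 0.007, g)
  expect_equal(suppression_efficiency(pre, post), 0.007, tolerance = 1e-9)
  zero <- mrs_spectrum(complex(g$n_points), g)
  expect_equal(suppression_efficiency(pre, zero), 0.0)
  expect_error(suppression_efficiency(zero, pre), "Zero pre-suppression")
})

test_that("QC filter partitions by the pass flag and conserves counts", {
  rep22 <- tibble::tibble(subject = sprintf("S%02d", 1:22),
                          fwhm_hz = seq(4, 7.9, length.out = 22),
                          snr = seq(12, 40, length.out = 22),
                          passed = TRUE)
  parts <- qc_filter(rep22)
  expect_equal(nrow(parts$kept), 22)
  expect_equal(nrow(parts$excluded), 0)

  mixed <- rep22
  mixed$fwhm_hz[3] <- 9
  mixed$passed[3] <- FALSE
  parts2 <- qc_filter(mixed)
  expect_equal(nrow(parts2$kept) + nrow(parts2$excluded), nrow(mixed))
  expect_true("S03" %in% parts2$excluded$subject)
  # multiset equality of the partition with the input
  expect_setequal(c(parts2$kept$subject, parts2$excluded$subject),
                  mixed$subject)

  empty <- qc_filter(rep22[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$excluded), 0)
})

test_that("qc_report applies boundary semantics (8 Hz and SNR 10 pass)", {
  g <- test_grid
  b <- single_line_basis("NAA")
  h_unit <- max(Re(b$components$NAA$spectrum$signal))
  tr <- ground_truth(setNames(200 / h_unit, "NAA"), noise_sd = 10, seed = 4)
  sp <- make_subject_spectrum(tr, b, g)$spectrum
  w8 <- make_water_reference(500, 8, g)
  rep <- qc_report(sp, w8, subject = "edge")
  expect_true(rep$passed)   # fwhm == 8 Hz is not "higher than 8"
  w9 <- make_water_reference(500, 9, g)
  expect_false(qc_report(sp, w9, subject = "wide")$passed)
})
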
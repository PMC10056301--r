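#' Zero-order phase correction
#'
#' Rotates the whole spectrum by a single global phase chosen to maximize
#' the integrated real part over the metabolite-dense 1.8-4.2 ppm window,
#' putting the spectrum in absorption mode. The maximizer has a closed
#' form: the integral of `Re(e^{i phi} S)` over the window is
#' `Re(e^{i phi} sum(S))`, maximal at `phi = -Arg(sum(S))`.
#'
#' @param spec An `mrs_spectrum` (nonzero).
#' @param window ppm window whose integrated real part is maximized.
#' @return List with `spectrum` (phased) and `phase0` (radians applied).
#' @export
zero_order_phase <- function(spec, window = c(1.8, 4.2)) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  idx <- ppm_window(spec$grid, window[1], window[2])
  s <- sum(spec$signal[idx])
  if (Mod(s) == 0) abort("Cannot phase an all-zero spectrum.")
  phi <- -Arg(s)
  list(spectrum = mrs_spectrum(spec$signal * exp(1i * phi), spec$grid,
                               spec$meta),
       phase0 = phi)
}

#' Water linewidth by Lorentzian fit
#'
#' Least-squares fit of a single Lorentzian (amplitude, center, FWHM,
#' constant offset free) to the real part in a +/-50 Hz window around the
#' water maximum of an unsuppressed spectrum; returns the FWHM in Hz, the
#' shim-quality metric of the exclusion filter.
#'
#' @param unsuppressed An `mrs_spectrum` whose global real-part maximum is
#'   the water peak.
#' @param window_hz Half-width of the fit window around the maximum.
#' @return FWHM in Hz.
#' @export
fit_water_fwhm <- function(unsuppressed, window_hz = 50) {
  stopifnot(inherits(unsuppressed, "mrs_spectrum"))
  grid <- unsuppressed$grid
  y <- Re(unsuppressed$signal)
  hz <- hz_axis(grid)
  imax <- which.max(y)
  idx <- which(abs(hz - hz[imax]) <= window_hz)
  xd <- hz[idx]
  yd <- y[idx]
  # half-height crossing gives the width start
  half <- (max(yd) + min(yd)) / 2
  w0 <- max(2 * grid$bandwidth / grid$n_points,
            diff(range(xd[yd >= half])))
  resid_fn <- function(p) {
    yd - (p[1] / (1 + (2 * (xd - p[2]) / p[3])^2) + p[4])
  }
  fit <- minpack.lm::nls.lm(
    par = c(a = max(yd) - min(yd), c0 = xd[which.max(yd)], w = w0,
            b = min(yd)),
    lower = c(0, xd[which.max(yd)] - window_hz, 1e-3, -Inf),
    upper = c(Inf, xd[which.max(yd)] + window_hz, 4 * window_hz, Inf),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  if (fit$info == 0 || fit$info == 5) {
    abort(sprintf("Water Lorentzian fit did not converge: %s (info %d)",
                  fit$message, fit$info))
  }
  unname(fit$par[["w"]])
}

#' Signal-to-noise ratio of a water-suppressed spectrum
#'
#' Peak height of the highest real-part signal between 0 and 3.4 ppm,
#' divided by the SD of the real part between 9 and 11 ppm after removing
#' a linear trend (which guards against baseline tilt in the noise
#' window).
#'
#' @param suppressed A phased `mrs_spectrum`; its grid must cover 0-11 ppm.
#' @param signal_window,noise_window ppm windows.
#' @return Dimensionless SNR.
#' @export
estimate_snr <- function(suppressed, signal_window = c(0, 3.4),
                         noise_window = c(9, 11)) {
  stopifnot(inherits(suppressed, "mrs_spectrum"))
  grid <- suppressed$grid
  ppm <- ppm_axis(grid)
  if (min(ppm) > signal_window[1] || max(ppm) < noise_window[2]) {
    abort("Grid must cover the 0-11 ppm range.")
  }
  y <- Re(suppressed$signal)
  sig <- max(y[ppm_window(grid, signal_window[1], signal_window[2])])
  ni <- ppm_window(grid, noise_window[1], noise_window[2])
  res <- stats::lm.fit(cbind(1, ppm[ni]), y[ni])$residuals
  nsd <- sd(res)
  if (nsd == 0) abort("Noise SD is zero; SNR undefined for noiseless input.")
  sig / nsd
}

#' Water-suppression efficiency
#'
#' Ratio of the water peak height after suppression to the height before
#' suppression; values well below 1% indicate good suppression.
#'
#' @param pre_spec,post_spec Phased spectra on the same grid
#'   (unsuppressed, suppressed).
#' @param water_window ppm window searched for the water maximum.
#' @return Proportion (post / pre).
#' @export
suppression_efficiency <- function(pre_spec, post_spec,
                                   water_window = c(4.2, 5.3)) {
  stopifnot(inherits(pre_spec, "mrs_spectrum"),
            inherits(post_spec, "mrs_spectrum"))
  if (!same_grid(pre_spec$grid, post_spec$grid)) abort("Grid mismatch.")
  idx <- ppm_window(pre_spec$grid, water_window[1], water_window[2])
  pre <- max(Re(pre_spec$signal)[idx])
  if (pre <= 0) abort("Zero pre-suppression water height.")
  max(Re(post_spec$signal)[idx]) / pre
}

#' Quality-control report for one subject
#'
#' Runs zero-order phasing, the water-linewidth fit, SNR estimation and
#' (when both water spectra are given) the suppression-efficiency measure,
#' and applies the exclusion rule: a spectrum passes when the water FWHM
#' is at most `fwhm_max` Hz and the SNR at least `snr_min` (the boundary
#' values pass; the filter excludes strictly beyond them).
#'
#' @param suppressed Water-suppressed `mrs_spectrum`.
#' @param unsuppressed Unsuppressed water reference `mrs_spectrum`.
#' @param subject Subject label.
#' @param fwhm_max,snr_min Exclusion thresholds (defaults 8 Hz, 10).
#' @return One-row tibble: `subject`, `fwhm_hz`, `snr`,
#'   `suppression_residual`, `phase0_applied`, `passed`.
#' @export
qc_report <- function(suppressed, unsuppressed, subject = "S01",
                      fwhm_max = 8, snr_min = 10) {
  ph <- zero_order_phase(suppressed)
  fwhm <- fit_water_fwhm(unsuppressed)
  snr <- estimate_snr(ph$spectrum)
  supp <- suppression_efficiency(unsuppressed, ph$spectrum)
  # boundary semantics: the filter excludes strictly beyond the
  # thresholds, so values at the threshold pass; a relative epsilon keeps
  # the boundary decision stable against solver round-off
  tibble::tibble(subject = subject, fwhm_hz = fwhm, snr = snr,
                 suppression_residual = supp, phase0_applied = ph$phase0,
                 passed = fwhm <= fwhm_max * (1 + 1e-6) &
                   snr >= snr_min * (1 - 1e-6))
}

#' Partition QC reports into kept and excluded subjects
#'
#' @param reports Tibble of QC rows (as from [qc_report()]) with a logical
#'   `passed` column.
#' @return List with tibbles `kept` and `excluded`; row counts conserved.
#' @export
qc_filter <- function(reports) {
  stopifnot(is.data.frame(reports))
  if (!nrow(reports)) {
    return(list(kept = tibble::as_tibble(reports),
                excluded = tibble::as_tibble(reports)))
  }
  list(kept = tibble::as_tibble(reports[reports$passed, , drop = FALSE]),
       excluded = tibble::as_tibble(reports[!reports$passed, , drop = FALSE]))
}
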
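#' Ground truth for a generated spectrum
#'
#' Every synthetic spectrum carries the parameters that generated it, so
#' downstream stages can be tested for parameter recovery. No pipeline
#' stage reads the ground truth; only tests do.
#'
#' @param concentrations Named numeric vector, component -> mM (>= 0).
#' @param baseline_coefficients Numeric vector of spline coefficients for
#'   the smooth baseline (empty for no baseline).
#' @param noise_sd SD of the complex Gaussian noise per frequency point.
#' @param water_amplitude Peak height of the residual water line (a.u.).
#' @param phase0 Zero-order phase error applied to the spectrum (radians).
#' @param seed RNG seed used for the noise draw.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(concentrations, baseline_coefficients = numeric(),
                         noise_sd = 0, water_amplitude = 0, phase0 = 0,
                         seed = NULL) {
  if (length(concentrations) && (is.null(names(concentrations)) ||
                                 any(!nzchar(names(concentrations))))) {
    abort("`concentrations` must be a named vector.")
  }
  if (any(concentrations < 0)) abort("Concentrations must be >= 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(list(concentrations = concentrations,
                 baseline_coefficients = baseline_coefficients,
                 noise_sd = noise_sd, water_amplitude = water_amplitude,
                 phase0 = phase0, seed = seed),
            class = "ground_truth")
}

# Smooth baseline: cubic B-spline with knots every 0.6 ppm across the
# metabolite region, evaluated from the given coefficients.
baseline_signal <- function(coefficients, grid, from = 0, to = 5) {
  n <- grid$n_points
  if (!length(coefficients)) return(numeric(n))
  ppm <- ppm_axis(grid)
  inner <- unique(c(seq(from, to, by = 0.6), to))
  knots <- c(from - 0.6 * (3:1), inner, to + 0.6 * (1:3))
  nb <- length(knots) - 4L
  if (length(coefficients) != nb) {
    abort(sprintf("Baseline needs %d coefficients, got %d.",
                  nb, length(coefficients)))
  }
  idx <- which(ppm >= from & ppm <= to)
  out <- numeric(n)
  B <- splines::splineDesign(knots, ppm[idx], ord = 4L)
  out[idx] <- drop(B %*% coefficients)
  out
}

#' Number of baseline coefficients expected by the subject generator
#' @param from,to ppm extent of the baseline region.
#' @return Integer count.
#' @export
n_baseline_coefficients <- function(from = 0, to = 5) {
  length(unique(c(seq(from, to, by = 0.6), to))) + 2L
}

#' Generate a subject spectrum with known ground truth
#'
#' Builds an in-vivo-like water-suppressed spectrum as the concentration-
#' weighted sum of basis components, plus a smooth spline baseline, a
#' residual water line at 4.8 ppm, and independent complex circular
#' Gaussian noise, the whole rotated by a zero-order phase error.
#'
#' @param truth A [ground_truth()]; every concentration must name a basis
#'   component.
#' @param basis A [basis_set()].
#' @param grid An [acq_grid()] matching the basis grid.
#' @param water_fwhm FWHM of the residual water line in Hz.
#' @return List with elements `spectrum` (an `mrs_spectrum`) and `truth`
#'   (the input, returned verbatim).
#' @export
make_subject_spectrum <- function(truth, basis, grid = basis$grid,
                                  water_fwhm = 8) {
  stopifnot(inherits(truth, "ground_truth"), inherits(basis, "basis_set"))
  if (!same_grid(grid, basis$grid)) abort("Grid mismatch with basis.")
  unknown <- setdiff(names(truth$concentrations), names(basis$components))
  if (length(unknown)) {
    abort(sprintf("Unknown basis component(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  sig <- complex(grid$n_points)
  for (m in names(truth$concentrations)) {
    sig <- sig + truth$concentrations[[m]] * basis$components[[m]]$spectrum$signal
  }
  sig <- sig + baseline_signal(truth$baseline_coefficients, grid)
  if (truth$water_amplitude != 0) {
    area <- truth$water_amplitude * pi * water_fwhm / 2
    sig <- sig + lorentz_line(hz_axis(grid), ppm_to_hz(4.8, grid),
                              water_fwhm, area = area)
  }
  if (truth$phase0 != 0) sig <- sig * exp(1i * truth$phase0)
  if (truth$noise_sd > 0) {
    sig <- sig + with_seed(truth$seed,
                           complex_noise(grid$n_points, truth$noise_sd))
  }
  list(spectrum = mrs_spectrum(sig, grid, meta = list(kind = "suppressed")),
       truth = truth)
}

#' Generate an unsuppressed water reference
#'
#' A single Lorentzian at the water chemical shift (4.7 ppm, the carrier)
#' whose `amplitude` is the peak height; its area (`amplitude * pi *
#' linewidth / 2`) is what water scaling reads.
#'
#' @param amplitude Peak height in a.u. (>= 0; 0 gives a zero spectrum,
#'   which downstream water scaling rejects).
#' @param linewidth Lorentzian FWHM in Hz (> 0).
#' @param grid An [acq_grid()].
#' @param center_ppm Water position; default 4.7.
#' @param noise_sd Optional complex noise SD.
#' @param seed Seed for the noise draw.
#' @return An `mrs_spectrum`.
#' @export
make_water_reference <- function(amplitude, linewidth, grid = acq_grid(),
                                 center_ppm = 4.7, noise_sd = 0, seed = NULL) {
  stopifnot_scalar_pos(linewidth, "linewidth")
  if (amplitude < 0) abort("`amplitude` must be >= 0.")
  sig <- lorentz_line(hz_axis(grid), ppm_to_hz(center_ppm, grid), linewidth,
                      area = amplitude * pi * linewidth / 2)
  if (noise_sd > 0) {
    sig <- sig + with_seed(seed, complex_noise(grid$n_points, noise_sd))
  }
  mrs_spectrum(sig, grid, meta = list(kind = "water_reference"))
}

#' Ideal water reference matched to the quantification constants
#'
#' Builds the unsuppressed water reference whose area equals
#' `2 * W_conc * ATT_H2O` in the same per-mM area units the basis
#' components use, so that water scaling of a noiseless matched fit
#' returns the generating concentrations exactly.
#'
#' @param config A [quant_config()].
#' @param linewidth Water FWHM in Hz.
#' @param grid An [acq_grid()].
#' @return An `mrs_spectrum`.
#' @export
ideal_water_reference <- function(config = quant_config(), linewidth = 5,
                                  grid = acq_grid()) {
  area <- 2 * config$W_conc * config$ATT_H2O
  make_water_reference(amplitude = area * 2 / (pi * linewidth),
                       linewidth = linewidth, grid = grid)
}

#' Generate the standard GE MRS phantom spectrum
#'
#' The phantom contains 12.5 mM NAA, 10 mM Cr, 3 mM Cho, 12.5 mM Glu,
#' 7.5 mM Ins and 5 mM Lac, no macromolecules and no baseline.
#'
#' @param grid An [acq_grid()].
#' @param basis A [basis_set()] containing NAA, Cr, Cho, Glu, Ins, Lac.
#' @param noise_sd Optional complex noise SD (default 0: noiseless).
#' @param seed Seed for the noise draw.
#' @return List with `spectrum` and `truth`.
#' @export
make_phantom_spectrum <- function(grid = acq_grid(),
                                  basis = phantom_basis(grid),
                                  noise_sd = 0, seed = NULL) {
  conc <- c(NAA = 12.5, Cr = 10, Cho = 3, Glu = 12.5, Ins = 7.5, Lac = 5)
  missing <- setdiff(names(conc), names(basis$components))
  if (length(missing)) {
    abort(sprintf("Basis lacks phantom component(s): %s",
                  paste(missing, collapse = ", ")))
  }
  full <- setNames(numeric(length(basis$components)), names(basis$components))
  full[names(conc)] <- conc
  truth <- ground_truth(full, noise_sd = noise_sd, seed = seed)
  make_subject_spectrum(truth, basis, grid)
}

#' Generate a masked VOI intensity map with a known CSF fraction
#'
#' Emulates the voxel intensities of a CSF probability map inside the
#' spectroscopy volume of interest: a two-class Gaussian mixture in which
#' exactly `round(n_voxels * csf_fraction)` voxels are drawn from the CSF
#' class. A warning flag is set when the class means are closer than three
#' pooled SDs, where Otsu thresholding becomes ill-posed.
#'
#' @param n_voxels Number of masked voxels.
#' @param csf_fraction True CSF proportion in `[0, 1]`.
#' @param class_params List of two `c(mean, sd)` pairs, tissue class first,
#'   CSF class second. The default emulates a near-binary CSF probability
#'   map: tissue voxels piled near 0, CSF voxels near 1.
#' @param seed RNG seed.
#' @return List with `intensities` (numeric), `csf_fraction` (the truth),
#'   `is_csf` (logical truth labels) and `separation_warning` (flag).
#' @export
make_voi_intensities <- function(n_voxels, csf_fraction,
                                 class_params = list(c(0.05, 0.05),
                                                     c(0.95, 0.05)),
                                 seed = NULL) {
  if (csf_fraction < 0 || csf_fraction > 1) {
    abort("`csf_fraction` must be in [0, 1].")
  }
  stopifnot_scalar_pos(n_voxels, "n_voxels")
  m <- vapply(class_params, `[`, numeric(1), 1L)
  s <- vapply(class_params, `[`, numeric(1), 2L)
  pooled <- sqrt(mean(s^2))
  sep_warn <- abs(diff(m)) <= 3 * pooled
  if (sep_warn) warn("Class means closer than 3 pooled SDs; Otsu is ill-posed.")
  n_csf <- round(n_voxels * csf_fraction)
  with_seed(seed, {
    x <- c(rnorm(n_voxels - n_csf, m[1], s[1]), rnorm(n_csf, m[2], s[2]))
    lab <- c(rep(FALSE, n_voxels - n_csf), rep(TRUE, n_csf))
    ord <- sample.int(n_voxels)
    list(intensities = x[ord], csf_fraction = csf_fraction,
         is_csf = lab[ord], separation_warning = sep_warn)
  })
}

#' Typical healthy-brain concentrations used by the cohort simulator
#'
#' Means (mM) and between-subject SDs for the prefrontal-cortex cohort
#' emulation; values are field-typical, not subject-specific.
#'
#' @return A tibble with columns `component`, `mean_mM`, `between_sd_mM`.
#' @export
brain_concentration_table <- function() {
  tibble::tribble(
    ~component, ~mean_mM, ~between_sd_mM,
    "NAA",  8.5, 0.9, "NAAG", 1.0, 0.3, "Cr",  4.5, 0.5, "PCr", 3.5, 0.5,
    "GPC",  0.8, 0.15, "PCh", 0.5, 0.12, "Glu", 8.0, 0.9, "Gln", 2.5, 0.6,
    "Ins",  5.5, 0.7, "GABA", 1.3, 0.4, "GSH", 1.8, 0.3, "Lac", 0.6, 0.2,
    "Tau",  1.2, 0.3, "Asp",  2.0, 0.5, "Ala", 0.3, 0.1, "Glc", 1.0, 0.3
  )
}

#' Simulate a spectroscopy cohort with known ground truth
#'
#' Draws per-subject concentrations around typical healthy-brain values
#' and generates a water-suppressed spectrum plus an unsuppressed water
#' reference for each subject.
#'
#' @param n_subjects Number of subjects.
#' @param basis A [basis_set()].
#' @param grid An [acq_grid()].
#' @param noise_sd Spectral noise SD (a.u. per point).
#' @param quant A [quant_config()] used to scale the water references.
#' @param concentration_table Tibble as [brain_concentration_table()],
#'   restricted to components present in `basis`.
#' @param phase_sd SD of the per-subject zero-order phase error (radians).
#' @param seed RNG seed; per-subject seeds are derived from it.
#' @return List of per-subject lists with elements `id`, `spectrum`,
#'   `water`, `truth`.
#' @export
simulate_cohort <- function(n_subjects, basis, grid = basis$grid,
                            noise_sd = 1, quant = quant_config(),
                            concentration_table = brain_concentration_table(),
                            phase_sd = 0.05, seed = 1) {
  tab <- concentration_table[
    concentration_table$component %in% names(basis$components), ]
  with_seed(seed, {
    sub_seeds <- sample.int(2^30, n_subjects)
    lapply(seq_len(n_subjects), function(i) {
      conc <- pmax(0, rnorm(nrow(tab), tab$mean_mM, tab$between_sd_mM))
      names(conc) <- tab$component
      truth <- ground_truth(conc, noise_sd = noise_sd,
                            water_amplitude = 0,
                            phase0 = rnorm(1, 0, phase_sd),
                            seed = sub_seeds[i])
      sub <- make_subject_spectrum(truth, basis, grid)
      list(id = sprintf("S%02d", i), spectrum = sub$spectrum,
           water = ideal_water_reference(quant, grid = grid),
           truth = truth)
    })
  })
}

#' Simulate a two-condition cohort concentration table
#'
#' Emulates the per-subject concentration and CRLB table produced by
#' fitting one cohort with two basis sets. Each subject's true
#' concentration is drawn once; each condition observes it with
#' independent measurement noise of SD `crlb_mM` (so the reported CRLB is
#' the true measurement SD). `delta_mM` injects a per-component systematic
#' offset into the second condition.
#'
#' @param n_subjects Number of subjects (rows per component/condition).
#' @param concentration_table As [brain_concentration_table()].
#' @param crlb_frac Measurement SD (= CRLB) as a fraction of the mean.
#' @param delta_mM Named vector of offsets added to condition
#'   `"simulated"`; unnamed scalar recycles to all components.
#' @param conditions Length-2 character vector of condition labels.
#' @param seed RNG seed.
#' @return A tidy cohort tibble with columns `subject`, `component`,
#'   `condition`, `conc_mM`, `crlb_mM`, `crlb_rel`.
#' @export
simulate_cohort_table <- function(n_subjects = 22,
                                  concentration_table = brain_concentration_table(),
                                  crlb_frac = 0.05, delta_mM = 0,
                                  conditions = c("in_house", "simulated"),
                                  seed = 1) {
  tab <- concentration_table
  with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(nrow(tab)), function(k) {
      comp <- tab$component[k]
      true_c <- pmax(0.05, rnorm(n_subjects, tab$mean_mM[k],
                                 tab$between_sd_mM[k]))
      crlb <- crlb_frac * tab$mean_mM[k]
      d <- if (!is.null(names(delta_mM))) {
        if (comp %in% names(delta_mM)) delta_mM[[comp]] else 0
      } else delta_mM
      purrr::map_dfr(seq_along(conditions), function(j) {
        obs <- true_c + rnorm(n_subjects, 0, crlb) + if (j == 2L) d else 0
        tibble::tibble(subject = sprintf("S%02d", seq_len(n_subjects)),
                       component = comp, condition = conditions[j],
                       conc_mM = obs, crlb_mM = crlb,
                       crlb_rel = 100 * crlb / mean(tab$mean_mM[k]))
      })
    })
    rows
  })
}
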
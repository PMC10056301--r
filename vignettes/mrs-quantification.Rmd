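---
title: "Methods: linear-combination quantification of brain MRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear-combination quantification of brain MRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsquant)
```

This vignette is the package's account of its science: the signal model,
the fitting and quantification procedures, what the synthetic-data
generator does and does not emulate, the numerical choices, and the known
limitations.

## Signal model and acquisition grid

Everything lives on a shared frequency axis defined by `acq_grid()`:
2048 complex points over a 2000 Hz bandwidth at a transmitter frequency
of 127.74 MHz (protons at 3.0 T), with the carrier assigned 4.7 ppm so
the water resonance sits at the center of the window. One ppm equals the
transmitter frequency in Hz. The axis is stored ascending; the
conventional MRS display (ppm decreasing left to right) is applied only
by the plotting methods. This grid covers roughly −3.1 to 12.5 ppm, which
matters because quality control reads signal in 0–3.4 ppm and noise in
9–11 ppm.

Metabolite resonances are modeled as complex Lorentzians
`L(ν) ∝ 1 / (1 + 2i(ν − ν₀)/w)` whose real part is the absorption line of
full width at half maximum `w` (Hz) and whose integrated absorption area
per unit concentration equals the number of contributing protons. The
chemical-shift/multiplet table shipped in
`inst/extdata/metabolite_lines.csv` uses standard literature positions
with each multiplet collapsed to a single line at its center —
first-order simplification, no density-matrix J-evolution. This is the
deliberate boundary of the simulator: strongly coupled patterns (Glu,
Gln, GABA) are narrower and simpler here than in reality, so fits on
synthetic data are easier than fits on scanner data, and passing recovery
tests demonstrates correctness of the estimation machinery, not in vivo
accuracy. Macromolecule/lipid components (MM09 … Lip20; names encode
their ppm) are single broad Gaussians with zero imaginary part, since no
implemented operation depends on their dispersion component.

## Synthetic data: what is emulated, what is not

`make_subject_spectrum()` builds a water-suppressed spectrum as

* the concentration-weighted sum of basis components,
* a smooth cubic-spline baseline with stated coefficients,
* a residual water Lorentzian at 4.8 ppm,
* independent complex circular Gaussian noise per frequency point,
* a global zero-order phase error,

and returns the generating `ground_truth()` verbatim. Generators are pure
functions of their parameters and seed — identical inputs give
bit-identical outputs — and nothing in the pipeline reads ground truth
except tests. Not emulated: pulse-sequence physics (PRESS/VAPOR), eddy
currents, frequency drift, coil combination, scanner raw formats.

The cohort simulator draws per-subject concentrations around typical
healthy-brain prefrontal values (`brain_concentration_table()`: NAA
8.5 ± 0.9 mM, Glu 8.0 ± 0.9 mM, Ins 5.5 ± 0.7 mM, …). The default
spectral noise in the test suite targets a signal-to-noise ratio of
roughly 20, comparable to a short-TE single-voxel acquisition.

`make_voi_intensities()` emulates the masked voxel intensities of a CSF
probability map inside the spectroscopy voxel as a two-class Gaussian
mixture with an exact number of CSF-class voxels,
`round(n_voxels × csf_fraction)`. The default classes, (0.05, 0.05) for
tissue and (0.95, 0.05) for CSF, reflect that segmentation posteriors are
near-binary; under this default the Otsu-based estimate is exact to a
voxel. A deliberately harder configuration — class means only five pooled
standard deviations apart — is used in the acceptance checks; see the
numerical notes below.

## Quality control

`qc_report()` runs, per subject:

* **zero-order phasing** — the global phase maximizing the integrated
  real part over 1.8–4.2 ppm. The maximizer has a closed form (the
  negative argument of the complex sum over the window), verified in the
  tests against a 3600-point grid search. The window choice is ours; the
  metabolite-dense region makes the criterion sensitive to the phase of
  the signals that matter.
* **water linewidth** — a four-parameter Lorentzian (amplitude, center,
  width, constant offset) least-squares fit in a ±50 Hz window around the
  water maximum of the unsuppressed spectrum, via the Levenberg–Marquardt
  residual interface (which, unlike the `nls()` formula interface,
  handles exactly noiseless inputs).
* **signal-to-noise ratio** — highest real-part signal in 0–3.4 ppm over
  the SD of the real part in 9–11 ppm after removing a linear trend (the
  detrend guards against baseline tilt in the noise window; whether to
  use the real part or the magnitude is not standardized, and the real
  part matches the phased-spectrum workflow).
* **suppression efficiency** — post/pre water peak-height ratio.

The exclusion rule keeps a subject when FWHM ≤ 8 Hz **and** SNR ≥ 10;
both thresholds are *pass-at-boundary* because exclusion is defined
strictly beyond them, and a relative epsilon of 10⁻⁶ keeps the boundary
decision stable against solver round-off.

## The fit

`fit_spectrum()` minimizes

`‖y − model‖² + α_B‖D²β‖² + α_S Σ(δ_m/δ_max)²`, `a_m ≥ 0`

with the model described in the README. Numerical design:

* **Separable structure.** Given the nuisance parameters (phase,
  broadening, shifts), the amplitudes and spline coefficients solve a
  penalized linear least-squares problem exactly — a Lawson–Hanson-style
  active set on the amplitude block (spline coefficients always free).
  The outer search over nuisance parameters is a bounded quasi-Newton
  (`nlminb`) on a **unit-scaled** parameter vector: phase in radians,
  broadening as a fraction of `max_broadening` (default 5 Hz), shifts as
  fractions of `max_shift` (default ±0.01 ppm). Without this scaling the
  Hessian is conditioned like (shift scale)⁻² ≈ 10⁴ and the search
  stalls.
* **Multi-start.** Three phase starts (the closed-form QC phase estimate,
  ±0.6 rad around it) guard against the sign-flipped local minimum at
  φ₀ + π, which non-negativity alone does not always exclude. A start
  whose objective already explains the data to solver precision
  (10⁻⁹·‖y‖²) short-circuits the rest, so noiseless fits cost one
  optimization.
* **Baseline.** Cubic B-spline with 0.15 ppm knot spacing over the fit
  range (0.2–4.0 ppm, the usual short-TE window), second-difference
  penalty on the coefficients. When `alpha_B` is not given it is chosen
  from the fixed grid 10⁻²…10⁶ by generalized cross-validation,
  `n·RSS/(n − edf)²`, computed once at the initial nuisance values and
  then held — a deliberate simplification of full per-iteration
  regularizer selection, traded for determinism and speed.
* **Degenerate inputs.** An all-zero spectrum fits to zero amplitudes and
  baseline; a singular Fisher information matrix raises an error naming
  the most collinear component pair; a metabolite-block condition number
  above 10⁸ is recorded as a warning in the result.

### Error bounds

`compute_crlb()` reports `σ·√diag[(JᵀJ)⁻¹]` over the amplitude block of
the linear design at the optimum, with `σ` estimated from the detrended
9–11 ppm residual unless supplied; bounds are propagated to mM through
the same area-ratio scaling as the concentrations. Two calibration facts
the tests enforce:

* The bound describes the *unpenalized* least-squares estimator. Under an
  active baseline penalty the realized amplitude variance is smaller
  (shrinkage), so the Monte-Carlo agreement check runs with `alpha_B = 0`,
  where bound and estimator describe the same procedure; there the CRLB
  matches the Monte-Carlo amplitude SD over 200 noise seeds within a few
  percent.
* Combined resonances (tCho = PCh+GPC, tNA = NAA+NAAG, tCr = Cr+PCr,
  Glx = Glu+Gln, and the MM/Lip sums) take their CRLB from the member
  covariance block, `√(1ᵀΣ1)` — not the quadrature sum — so strongly
  anti-correlated members yield a sum better determined than either
  member, which is the point of reporting sums.

## Quantification

Water scaling uses the standard constants (`W_conc` 35880 mmol/L,
`ATT_H2O` 0.7, `ATT_met` 1.0 per metabolite unless configured). The area
ratio is implemented as *metabolite-to-water*: the alternative orientation
would not produce mM-scale outputs. Both areas are numeric real-part
integrals on the same grid, so grid-truncation of Lorentzian tails
(≈0.1–0.3%) largely cancels in the ratio. `ideal_water_reference()`
constructs the unsuppressed reference whose area equals
`2·W_conc·ATT_H2O` in the basis's per-mM units, making the noiseless
matched round trip exact by construction — that is a property of the
simulator's self-consistency, not evidence about scanner calibration.

CSF correction divides by `1 − CSF_VOI`. The fraction comes from Otsu
thresholding (256-bin histogram, min–max scaled, ties averaged) of the
CSF probability map inside the VOI, counting **above**-threshold voxels
of that map as CSF. Wording that describes above-threshold intensities as
"tissue" appears when thresholding anatomical images; applying Otsu to
the CSF probability map keeps the rule consistent with counting CSF.

A known estimator limitation, documented rather than hidden: with *equal*
class SDs and 95%/5% class imbalance, Otsu's threshold sits ≈2.3σ from
the large-class mean, so at exactly five pooled SDs of separation about
1% of tissue voxels cross it and a 5% fraction reads ≈6%. Realistic
probability maps do not look like that — the tissue class is much
narrower than the partial-volume CSF class — and under the package's
class configuration (tissue SD 0.03, CSF SD 0.12 at five pooled SDs) the
estimate is 4.8% for a true 5%. At the near-binary default separation
recovery is exact to ±1 voxel.

## Cohort statistics

`compare_conditions()` runs, per component, a paired t-test when the
paired differences pass a Shapiro–Wilk screen at 0.05, otherwise the
Wilcoxon signed-rank test (the signed-rank test is the paired member of
the rank-test family; the rank-sum/Mann–Whitney test applies to
independent samples and is not used). The t-based 95% CI of the mean
paired difference is always reported alongside, with significance stars
at 0.05/0.01/0.001. Correlation matrices are Pearson, masked at p ≥ 0.1,
symmetric with unit diagonal; zero-variance components are masked with a
warning. The coefficient of variation is the conventional
`100·SD/mean` with the n−1 SD (a published description inverting the
ratio behaves, in its reported values, as SD/mean percent). The
CV-vs-CRLB classification calls a component CV-dominant when
between-subject CV strictly exceeds the mean relative CRLB (ties are
CRLB-dominant — measurement error at least as large as biological
spread), and bins components by mean CRLB at 15% and 35%.

Two calibration properties worth stating precisely:

* The t-based CI of the mean paired difference covers an injected offset
  in 93–97% of 500 seeded cohorts (n = 22), as the tests assert.
* For the null cohort, the pipeline's two conditions fit the *same*
  spectra with the *same* basis, so every paired difference is exactly
  zero and no component is starred. A harsher null — each condition
  observing the subject's concentration with independent measurement
  noise — is a correctly calibrated 5%-level procedure: its long-run star
  rate is the nominal 5% by construction, so no finite seed set can
  guarantee it stays below 5%, and the package does not pretend otherwise.

## Problem sizes

The test suite runs entirely on synthetic data at sizes chosen to make
every property checkable in seconds: full 2048-point grids throughout;
single fits for exactness properties; 12-spectrum cohorts for
parameter-recovery medians; 200 noise seeds for the CRLB/Monte-Carlo
agreement; 100–500 seeds for calibration rates; 22-subject cohorts
wherever the statistics depend on n. The acceptance script re-derives the
phantom composition, the CSF percentage and the boundary linewidth from
scratch at the same sizes.

## Limitations

* Basis spectra are first-order multiplets; no J-evolution, no
  field-/TE-dependent lineshape of strongly coupled spins.
* One global Lorentzian broadening and zero-order phase; no first-order
  phase, no flexible lineshape deconvolution, no eddy-current model.
* Constant attenuation factors stand in for T1/T2 relaxation correction;
  no metabolite-nulled macromolecule acquisition.
* The baseline weight is selected once by GCV on a fixed grid, not
  re-optimized within the nuisance search.
* No multiple-testing correction across components in the cohort layer —
  the comparison design under study reports per-component tests.
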
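#' Quantification constants
#'
#' Constants of the water-scaling equation
#' `Conc = Ratio_area * (2 / N1H_met) * (ATT_H2O / ATT_met) * W_conc`.
#'
#' @param W_conc Water concentration in the VOI, mmol/L (default 35880,
#'   the conventional brain value).
#' @param ATT_H2O Water signal attenuation factor (default 0.7).
#' @param ATT_met Metabolite attenuation; scalar or named vector
#'   (default 1.0, i.e. fully relaxed metabolite signal).
#' @param N1H Named map metabolite -> proton count; when `NULL` it is
#'   taken from the basis components at quantification time.
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(W_conc = 35880, ATT_H2O = 0.7, ATT_met = 1.0,
                         N1H = NULL) {
  stopifnot_scalar_pos(W_conc, "W_conc")
  stopifnot_scalar_pos(ATT_H2O, "ATT_H2O")
  if (any(ATT_met <= 0)) abort("`ATT_met` must be positive.")
  structure(list(W_conc = W_conc, ATT_H2O = ATT_H2O, ATT_met = ATT_met,
                 N1H = N1H), class = "quant_config")
}

att_met_for <- function(config, metabolite) {
  if (length(config$ATT_met) == 1L && is.null(names(config$ATT_met))) {
    return(config$ATT_met)
  }
  if (metabolite %in% names(config$ATT_met)) config$ATT_met[[metabolite]]
  else 1.0
}

#' Water-scaled absolute concentration
#'
#' Applies the water-scaling equation to a metabolite-to-water area
#' ratio. `ratio_area` is the fitted metabolite peak area divided by the
#' unsuppressed water peak area.
#'
#' @param ratio_area Metabolite-to-water area ratio (>= 0).
#' @param metabolite Metabolite name (must be in the N1H map).
#' @param config A [quant_config()] with a populated `N1H` map.
#' @return Concentration in mM.
#' @examples
#' cfg <- quant_config(N1H = c(NAA = 3))
#' water_scale(1e-4, "NAA", cfg)
#' @export
water_scale <- function(ratio_area, metabolite, config) {
  if (ratio_area < 0) abort("`ratio_area` must be >= 0.")
  if (is.null(config$N1H) || !(metabolite %in% names(config$N1H))) {
    abort(sprintf("No N1H proton count for metabolite '%s'.", metabolite))
  }
  n1h <- config$N1H[[metabolite]]
  ratio_area * (2 / n1h) * (config$ATT_H2O / att_met_for(config, metabolite)) *
    config$W_conc
}

#' Quantify a fit against a water reference
#'
#' Converts fitted amplitudes to absolute concentrations: each
#' component's area per amplitude unit is integrated from its basis
#' spectrum, divided by the integrated unsuppressed water area, and
#' passed through [water_scale()]. CRLBs are propagated through the same
#' chain to mM and %SD.
#'
#' @param result An `mrs_fit` from [fit_spectrum()].
#' @param basis The [basis_set()] used in the fit.
#' @param water Unsuppressed water reference `mrs_spectrum`.
#' @param config A [quant_config()]; its `N1H` map defaults to the basis
#'   proton counts.
#' @param csf_fraction Optional CSF fraction for partial-volume
#'   correction of all concentrations (see [csf_correct()]).
#' @return The fit with `concentrations`, `crlb_abs`, `crlb_rel` filled.
#' @export
quantify_fit <- function(result, basis, water, config = quant_config(),
                         csf_fraction = 0) {
  stopifnot(inherits(result, "mrs_fit"), inherits(water, "mrs_spectrum"))
  water_area <- spec_area(water$signal, water$grid)
  if (water_area <= 0) abort("Water reference area must be positive.")
  nm <- names(result$amplitudes)
  if (is.null(config$N1H)) {
    config$N1H <- vapply(basis$components[nm],
                         function(x) x$protons_at_reference, numeric(1))
  }
  areas <- vapply(basis$components[nm],
                  function(x) spec_area(x$spectrum$signal, x$grid), numeric(1))
  scale <- vapply(nm, function(m) {
    water_scale(areas[[m]] / water_area, m, config)
  }, numeric(1))
  conc <- result$amplitudes * scale
  if (csf_fraction > 0) {
    conc <- csf_correct(conc, csf_fraction)
    scale <- scale / (1 - csf_fraction)
  }
  result$scale_mM <- scale
  result$concentrations <- conc
  if (!is.null(result$noise_sd) && !is.na(result$noise_sd)) {
    cr <- compute_crlb(result)
    result$crlb_abs <- cr$crlb_abs
    result$crlb_rel <- cr$crlb_rel
  }
  result
}

#' Otsu threshold of an intensity distribution
#'
#' Finds the threshold maximizing the between-class variance over a
#' 256-bin histogram of the intensities (min-max scaled). Ties are broken
#' by averaging the maximizing bin boundaries.
#'
#' @param intensities Numeric vector with at least two distinct values.
#' @param n_bins Histogram bins (default 256).
#' @return Threshold intensity; classification is `x > threshold`.
#' @export
otsu_threshold <- function(intensities, n_bins = 256L) {
  x <- intensities[is.finite(intensities)]
  if (length(unique(x)) < 2L) abort("Otsu needs >= 2 distinct values.")
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE),
                          1L), n_bins), n_bins)
  p <- h / sum(h)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[n_bins]
  k <- seq_len(n_bins - 1L)
  denom <- w0[k] * (1 - w0[k])
  sigma_b <- ifelse(denom > 0, (muT * w0[k] - mu0[k])^2 / denom, -Inf)
  best <- which(sigma_b == max(sigma_b))
  mean(breaks[best + 1L])
}

#' CSF fraction of a VOI from a probability-map intensity array
#'
#' Applies [otsu_threshold()] to the masked CSF probability-map
#' intensities inside the VOI and counts above-threshold voxels as CSF;
#' the fraction is `N_CSF / N_VOI`.
#'
#' @param intensities Masked voxel intensities (non-empty).
#' @return List of class `segmentation_voi`: `intensities`, `threshold`,
#'   `n_csf`, `n_voi`, `csf_fraction`.
#' @export
csf_fraction <- function(intensities) {
  if (!length(intensities)) abort("Empty VOI mask.")
  thr <- otsu_threshold(intensities)
  n_csf <- sum(intensities > thr)
  structure(list(intensities = intensities, threshold = thr,
                 n_csf = n_csf, n_voi = length(intensities),
                 csf_fraction = n_csf / length(intensities)),
            class = "segmentation_voi")
}

#' @export
print.segmentation_voi <- function(x, ...) {
  cat(sprintf("<segmentation_voi> %d / %d voxels CSF (%.2f%%), threshold %.3g\n",
              x$n_csf, x$n_voi, 100 * x$csf_fraction, x$threshold))
  invisible(x)
}

#' Tidy a VOI segmentation
#' @param x A `segmentation_voi`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.segmentation_voi <- function(x, ...) {
  tibble::tibble(n_voi = x$n_voi, n_csf = x$n_csf,
                 threshold = x$threshold, csf_fraction = x$csf_fraction)
}

#' CSF partial-volume correction
#'
#' Rescales a measured concentration for the metabolite-free CSF portion
#' of the VOI: `Conc_corrected = Conc_measured / (1 - CSF_VOI)`.
#'
#' @param conc_measured Concentration(s) in mM.
#' @param csf_fraction CSF proportion in `[0, 1)`.
#' @return Corrected concentration(s) in mM.
#' @export
csf_correct <- function(conc_measured, csf_fraction) {
  if (csf_fraction < 0 || csf_fraction >= 1) {
    abort("`csf_fraction` must be in [0, 1).")
  }
  conc_measured / (1 - csf_fraction)
}
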
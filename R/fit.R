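#' Fit configuration
#'
#' Tunable parameters of the linear-combination fit.
#'
#' @param fit_range ppm interval fitted (default 0.2-4.0 ppm, the usual
#'   short-TE metabolite window).
#' @param baseline_knot_spacing Knot spacing of the cubic B-spline
#'   baseline, in ppm (default 0.15); `NULL` fits without any baseline.
#' @param alpha_B Baseline regularization weight on the squared second
#'   differences of the spline coefficients; `NULL` (default) selects a
#'   value from `alpha_B_grid` by generalized cross-validation.
#' @param alpha_B_grid Candidate weights for the GCV selection.
#' @param alpha_S Penalty weight on the per-component frequency shifts
#'   (applied to shifts in units of `max_shift`).
#' @param max_broadening Upper bound on the global Lorentzian broadening
#'   added to the basis, in Hz.
#' @param max_shift Bound on per-component frequency shifts, in ppm;
#'   set to 0 to disable shift estimation.
#' @param nonneg Enforce non-negative amplitudes.
#' @param n_starts Number of phase multi-starts.
#' @param seed Seed controlling any randomized start jitter.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(fit_range = c(0.2, 4.0), baseline_knot_spacing = 0.15,
                       alpha_B = NULL,
                       alpha_B_grid = 10^seq(-2, 6, by = 2),
                       alpha_S = 1, max_broadening = 5, max_shift = 0.01,
                       nonneg = TRUE, n_starts = 3L, seed = 1L) {
  if (!is.null(alpha_B) && alpha_B < 0) abort("`alpha_B` must be >= 0.")
  if (alpha_S < 0) abort("`alpha_S` must be >= 0.")
  if (diff(fit_range) <= 0) abort("`fit_range` must be an increasing interval.")
  structure(list(fit_range = fit_range,
                 baseline_knot_spacing = baseline_knot_spacing,
                 alpha_B = alpha_B, alpha_B_grid = alpha_B_grid,
                 alpha_S = alpha_S, max_broadening = max_broadening,
                 max_shift = max_shift, nonneg = isTRUE(nonneg),
                 n_starts = as.integer(n_starts), seed = seed),
            class = "fit_config")
}

# Cubic B-spline design for the baseline over the fit range.
baseline_design <- function(grid, idx, fit_range, spacing) {
  ppm <- ppm_axis(grid)[idx]
  inner <- seq(fit_range[1], fit_range[2], by = spacing)
  step <- spacing
  knots <- c(fit_range[1] - step * (3:1), inner, fit_range[2] + step * (1:3))
  splines::splineDesign(knots, ppm, ord = 4L, outer.ok = TRUE)
}

second_diff_matrix <- function(p) {
  if (p < 3) return(matrix(0, 0, p))
  D <- matrix(0, p - 2, p)
  for (i in seq_len(p - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  D
}

# Penalized least squares with non-negativity on the first `n_amp`
# coefficients: min ||y - X b||^2 + alpha ||D b_spline||^2, b[1:n_amp] >= 0.
# Lawson-Hanson style active set on the amplitude block; spline
# coefficients are always free.
solve_penalized_nnls <- function(X, y, n_amp, Dpen, alpha, nonneg = TRUE,
                                 tol = NULL) {
  p <- ncol(X)
  Xa <- X
  ya <- y
  if (nrow(Dpen) > 0 && alpha > 0) {
    P <- matrix(0, nrow(Dpen), p)
    P[, (n_amp + 1):p] <- sqrt(alpha) * Dpen
    Xa <- rbind(X, P)
    ya <- c(y, numeric(nrow(Dpen)))
  }
  if (is.null(tol)) tol <- 1e-10 * max(abs(ya), 1)
  clamped <- rep(FALSE, p)
  beta <- numeric(p)
  for (iter in seq_len(4L * n_amp + 4L)) {
    free <- which(!clamped)
    bf <- qr.coef(qr(Xa[, free, drop = FALSE]), ya)
    bf[is.na(bf)] <- 0
    beta <- numeric(p)
    beta[free] <- bf
    if (!nonneg) break
    neg <- which(beta[seq_len(n_amp)] < -tol)
    if (length(neg)) {
      clamped[neg[which.min(beta[neg])]] <- TRUE
      next
    }
    beta[seq_len(n_amp)][beta[seq_len(n_amp)] < 0] <- 0
    cl <- which(clamped)
    if (length(cl)) {
      g <- drop(crossprod(Xa[, cl, drop = FALSE], ya - Xa %*% beta))
      rel <- which(g > tol * 10)
      if (length(rel)) {
        clamped[cl[rel[which.max(g[rel])]]] <- FALSE
        next
      }
    }
    break
  }
  beta
}

# Modified basis columns (real part on fit-range rows) for nuisance
# parameters theta: global phase, global Lorentzian broadening, and
# per-component frequency shifts (Hz).
basis_columns <- function(fids, grid, idx, phase0, broaden_hz, shifts_hz) {
  t <- fid_time(grid)
  tw <- pmin(t, grid$n_points / grid$bandwidth - t)
  decay <- exp(-pi * broaden_hz * tw)
  ph <- exp(1i * phase0)
  cols <- vapply(seq_along(fids), function(m) {
    fid <- fids[[m]] * decay
    if (shifts_hz[m] != 0) fid <- fid * exp(2i * pi * shifts_hz[m] * t)
    Re(ph * fid_spec(fid, grid))[idx]
  }, numeric(length(idx)))
  cols
}

gcv_alpha <- function(X, y, n_amp, Dpen, grid_alpha) {
  n <- length(y)
  p <- ncol(X)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  PtP <- matrix(0, p, p)
  sp <- (n_amp + 1):p
  PtP[sp, sp] <- crossprod(Dpen)
  scores <- vapply(grid_alpha, function(a) {
    A <- XtX + a * PtP
    bi <- tryCatch(solve(A, cbind(Xty, t(X))), error = function(e) NULL)
    if (is.null(bi)) return(Inf)
    beta <- bi[, 1]
    H <- X %*% bi[, -1, drop = FALSE]
    edf <- sum(diag(H))
    rss <- sum((y - X %*% beta)^2)
    n * rss / (n - edf)^2
  }, numeric(1))
  grid_alpha[which.min(scores)]
}

#' Predict a spectrum from explicit model parameters
#'
#' Evaluates the linear-combination model on the fit range: the sum of
#' amplitude-scaled, phase-rotated, broadened and shifted basis
#' components plus the spline baseline.
#'
#' @param params List with elements `amplitudes` (named, one per basis
#'   component), `spline_coefficients`, and optional `phase0` (rad),
#'   `broadening` (Hz), `shifts` (named, ppm).
#' @param basis A [basis_set()].
#' @param config A [fit_config()].
#' @return Numeric vector: the real-valued prediction on the fit range.
#' @export
model_predict <- function(params, basis, config = fit_config()) {
  grid <- basis$grid
  nm <- names(basis$components)
  if (!setequal(names(params$amplitudes), nm)) {
    abort("`params$amplitudes` must name every basis component.")
  }
  idx <- ppm_window(grid, config$fit_range[1], config$fit_range[2])
  B <- if (is.null(config$baseline_knot_spacing)) {
    matrix(0, length(idx), 0)
  } else {
    baseline_design(grid, idx, config$fit_range,
                    config$baseline_knot_spacing)
  }
  if (length(params$spline_coefficients) &&
      length(params$spline_coefficients) != ncol(B)) {
    abort(sprintf("Expected %d spline coefficients.", ncol(B)))
  }
  shifts <- setNames(rep(0, length(nm)), nm)
  if (!is.null(params$shifts)) shifts[names(params$shifts)] <- params$shifts
  fids <- lapply(basis$components,
                 function(cmp) spec_fid(cmp$spectrum$signal, grid))
  X <- basis_columns(fids, grid, idx,
                     phase0 = params$phase0 %||% 0,
                     broaden_hz = params$broadening %||% 0,
                     shifts_hz = shifts[nm] * grid$transmitter_freq)
  out <- drop(X %*% params$amplitudes[nm])
  if (length(params$spline_coefficients)) {
    out <- out + drop(B %*% params$spline_coefficients)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a spectrum by regularized linear combination of basis components
#'
#' Minimizes
#' `||y - model||^2 + alpha_B ||D2 spline||^2 + alpha_S ||shift/max_shift||^2`
#' over non-negative component amplitudes, cubic B-spline baseline
#' coefficients, a global zero-order phase, a global Lorentzian
#' broadening, and bounded per-component frequency shifts. The linear
#' block (amplitudes + baseline) is solved exactly at each step of the
#' bounded quasi-Newton search over the nuisance parameters; phase
#' multi-starts guard against local minima. When `config$alpha_B` is
#' `NULL`, the baseline weight is selected once by generalized
#' cross-validation on a fixed grid and then held.
#'
#' @param spec An `mrs_spectrum` (assumed to have passed QC; not enforced).
#' @param basis A [basis_set()] on the same grid.
#' @param config A [fit_config()].
#' @param noise_sd Optional known noise SD (a.u. per point); estimated
#'   from the 9-11 ppm window when `NULL`.
#' @return An object of class `mrs_fit`; see [tidy.mrs_fit()].
#' @export
fit_spectrum <- function(spec, basis, config = fit_config(), noise_sd = NULL) {
  stopifnot(inherits(spec, "mrs_spectrum"), inherits(basis, "basis_set"))
  if (!same_grid(spec$grid, basis$grid)) abort("Grid mismatch with basis.")
  grid <- spec$grid
  nm <- names(basis$components)
  n_amp <- length(nm)
  idx <- ppm_window(grid, config$fit_range[1], config$fit_range[2])
  fids <- lapply(basis$components,
                 function(cmp) spec_fid(cmp$spectrum$signal, grid))
  B <- if (is.null(config$baseline_knot_spacing)) {
    matrix(0, length(idx), 0)
  } else {
    baseline_design(grid, idx, config$fit_range,
                    config$baseline_knot_spacing)
  }
  Dpen <- second_diff_matrix(ncol(B))
  f0 <- grid$transmitter_freq

  use_shift <- config$max_shift > 0
  use_broad <- config$max_broadening > 0
  n_shift <- if (use_shift) n_amp else 0L

  y_full <- spec$signal
  phi_init <- tryCatch(zero_order_phase(spec)$phase0, error = function(e) 0)

  # The outer parameter vector is unit-scaled for conditioning:
  # theta = (phase0 [rad], broadening / max_broadening, shifts / max_shift).
  build_X <- function(theta) {
    phase0 <- theta[1]
    gamma <- if (use_broad) theta[2] * config$max_broadening else 0
    shifts_ppm <- if (use_shift) {
      theta[(2 + use_broad):(1 + use_broad + n_amp)] * config$max_shift
    } else rep(0, n_amp)
    Xm <- basis_columns(fids, grid, idx, phase0, gamma, shifts_ppm * f0)
    list(X = cbind(Xm, B), shifts = shifts_ppm, phase0 = phase0,
         gamma = gamma)
  }
  # The model rotates the basis, not the data: we fit the real part of the
  # data and let phase0 rotate the basis columns to match.
  y <- Re(y_full)[idx]

  # alpha_B: select once by GCV at the initial nuisance values.
  alpha_B <- config$alpha_B
  if (ncol(B) == 0L) alpha_B <- 0
  if (is.null(alpha_B)) {
    X0 <- build_X(c(phi_init, if (use_broad) 0.5, numeric(n_shift)))$X
    alpha_B <- gcv_alpha(X0, y, n_amp, Dpen, config$alpha_B_grid)
  }

  shift_pen_scale <- if (use_shift) {
    config$alpha_S * mean(y^2) * length(y) / max(n_amp, 1)
  } else 0

  objective <- function(theta) {
    bx <- build_X(theta)
    beta <- solve_penalized_nnls(bx$X, y, n_amp, Dpen, alpha_B,
                                 nonneg = config$nonneg)
    r <- y - drop(bx$X %*% beta)
    pen_b <- if (alpha_B > 0 && nrow(Dpen) > 0) {
      alpha_B * sum((Dpen %*% beta[(n_amp + 1):length(beta)])^2)
    } else 0

    pen_s <- if (use_shift && config$max_shift > 0) {
      shift_pen_scale * sum((bx$shifts / config$max_shift)^2)
    } else 0
    sum(r^2) + pen_b + pen_s
  }

  lower <- c(-pi, if (use_broad) 0, rep(-1, n_shift))
  upper <- c(pi, if (use_broad) 1, rep(1, n_shift))
  starts <- with_seed(config$seed, {
    dphi <- c(0, 0.6, -0.6, runif(max(0, config$n_starts - 3L), -pi, pi))
    lapply(dphi[seq_len(max(1L, config$n_starts))], function(d) {
      c(wrap_angle(phi_init + d), if (use_broad) 0.02, numeric(n_shift))
    })
  })

  best <- NULL
  for (th0 in starts) {
    opt <- nlminb(th0, objective, lower = lower, upper = upper,
                  control = list(rel.tol = 1e-12, iter.max = 400))
    if (is.null(best) || opt$objective < best$objective) best <- opt
    # a start that already explains the data to solver precision makes
    # further starts pointless
    if (best$objective < 1e-9 * sum(y^2)) break
  }
  theta <- best$par

  bx <- build_X(theta)
  beta <- solve_penalized_nnls(bx$X, y, n_amp, Dpen, alpha_B,
                               nonneg = config$nonneg)
  amplitudes <- setNames(pmax(0, beta[seq_len(n_amp)]), nm)
  spl <- if (length(beta) > n_amp) beta[(n_amp + 1):length(beta)]
         else numeric(0)
  baseline <- if (ncol(B)) drop(B %*% spl) else numeric(length(idx))
  fitted <- drop(bx$X %*% beta)
  residual <- y - fitted

  # conditioning check on the metabolite block
  sv <- svd(bx$X[, seq_len(n_amp), drop = FALSE], nu = 0, nv = 0)$d
  cond <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  warning_flag <- if (cond > 1e8) "ill-conditioned basis" else NA_character_

  if (is.null(noise_sd)) {
    ni <- ppm_window(grid, 9, 11)
    noise_sd <- if (length(ni) > 8) {
      sd(stats::lm.fit(cbind(1, ni), Re(y_full)[ni])$residuals)
    } else NA_real_
  }

  # unit covariance of the amplitude block: sigma^2 * (J'J)^-1 sub-block
  J <- bx$X
  JtJ <- crossprod(J)
  cov_unit <- tryCatch(solve(JtJ)[seq_len(n_amp), seq_len(n_amp),
                                  drop = FALSE],
                       error = function(e) {
    cc <- abs(stats::cor(J[, seq_len(n_amp), drop = FALSE]))
    diag(cc) <- 0
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    abort(sprintf("Singular Fisher information; collinear components: %s, %s",
                  nm[worst[1]], nm[worst[2]]))
  })
  dimnames(cov_unit) <- list(nm, nm)

  structure(list(
    amplitudes = amplitudes,
    concentrations = NULL, crlb_abs = NULL, crlb_rel = NULL,
    baseline = baseline, fitted = fitted, residual = residual,
    spline_coefficients = spl,
    phase0 = bx$phase0, global_broadening = bx$gamma,
    shifts = setNames(bx$shifts, nm),
    alpha_S_used = config$alpha_S, alpha_B_used = alpha_B,
    covariance_unit = cov_unit, noise_sd = noise_sd,
    scale_mM = NULL, combinations = NULL,
    idx = idx, ppm = ppm_axis(grid)[idx], y = y,
    grid = grid, basis_names = nm, config = config,
    condition_number = cond, warning = warning_flag,
    objective = best$objective, convergence = best$convergence
  ), class = "mrs_fit")
}

wrap_angle <- function(x) ((x + pi) %% (2 * pi)) - pi

#' @export
print.mrs_fit <- function(x, ...) {
  cat(sprintf("<mrs_fit> %d components, RMS residual %.3g, phase %.3f rad\n",
              length(x$amplitudes), sqrt(mean(x$residual^2)), x$phase0))
  if (!is.na(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Cramer-Rao lower bounds of the fitted amplitudes
#'
#' Computes `sqrt(diag((J'J)^-1)) * noise_sd` for the amplitude block of
#' the model Jacobian at the optimum. When the fit has been water-scaled
#' (see [quantify_fit()]) the bounds are propagated through the same
#' scaling chain and returned in mM with relative bounds in %SD; before
#' scaling they are in amplitude units.
#'
#' @param result An `mrs_fit`.
#' @param noise_sd Noise SD per point; defaults to the value stored in the
#'   fit (estimated from 9-11 ppm).
#' @return List with `crlb_abs` and `crlb_rel` (the latter `NA` until
#'   concentrations exist).
#' @export
compute_crlb <- function(result, noise_sd = result$noise_sd) {
  stopifnot(inherits(result, "mrs_fit"))
  if (is.null(noise_sd) || is.na(noise_sd)) {
    abort("`noise_sd` is unknown; supply it explicitly.")
  }
  crlb_amp <- sqrt(pmax(diag(result$covariance_unit), 0)) * noise_sd
  if (!is.null(result$scale_mM)) {
    crlb_abs <- crlb_amp * result$scale_mM[names(crlb_amp)]
    conc <- result$concentrations[names(crlb_abs)]
    crlb_rel <- ifelse(conc > 0, 100 * crlb_abs / conc, NA_real_)
    list(crlb_abs = crlb_abs, crlb_rel = crlb_rel)
  } else {
    list(crlb_abs = crlb_amp,
         crlb_rel = ifelse(result$amplitudes > 0,
                           100 * crlb_amp / result$amplitudes, NA_real_))
  }
}

#' Report combined resonances on a quantified fit
#'
#' For every combination rule in the basis (tCho, tNA, tCr, Glx and the
#' macromolecule/lipid sums) whose members were fitted, adds the summed
#' concentration and its CRLB computed from the member covariance
#' sub-block, `sqrt(1' Sigma 1)` - not the quadrature sum of member
#' CRLBs, so anti-correlated members yield a better-determined sum.
#'
#' @param result A quantified `mrs_fit` (run [quantify_fit()] first).
#' @param basis The [basis_set()] used for the fit.
#' @return The fit with a `combinations` tibble attached.
#' @export
combine_metabolites <- function(result, basis) {
  stopifnot(inherits(result, "mrs_fit"))
  if (is.null(result$concentrations)) {
    abort("Quantify the fit (quantify_fit) before combining metabolites.")
  }
  combos <- basis$combinations
  sigma_mM <- result$noise_sd^2 *
    (result$scale_mM %o% result$scale_mM) * result$covariance_unit
  rows <- purrr::map_dfr(names(combos), function(cn) {
    members <- combos[[cn]]
    if (!all(members %in% names(result$concentrations))) {
      abort(sprintf("Combination %s has missing member(s).", cn))
    }
    v <- sum(sigma_mM[members, members])
    conc <- sum(result$concentrations[members])
    crlb <- sqrt(max(0, v))
    tibble::tibble(component = cn, conc_mM = conc, crlb_mM = crlb,
                   crlb_rel = if (conc > 0) 100 * crlb / conc else NA_real_)
  })
  result$combinations <- rows
  result
}

#' Tidy and summarize a fit
#'
#' `tidy()` returns one row per component (and per combination, when
#' present) with amplitude, concentration and CRLBs; `glance()` a one-row
#' fit summary.
#'
#' @param x An `mrs_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mrs_fit <- function(x, ...) {
  out <- tibble::tibble(
    component = names(x$amplitudes),
    amplitude = unname(x$amplitudes),
    conc_mM = if (is.null(x$concentrations)) NA_real_
              else unname(x$concentrations[names(x$amplitudes)]),
    crlb_mM = if (is.null(x$crlb_abs)) NA_real_
              else unname(x$crlb_abs[names(x$amplitudes)]),
    crlb_rel = if (is.null(x$crlb_rel)) NA_real_
               else unname(x$crlb_rel[names(x$amplitudes)]),
    is_combination = FALSE)
  if (!is.null(x$combinations) && nrow(x$combinations)) {
    out <- dplyr::bind_rows(out, dplyr::mutate(
      x$combinations, amplitude = NA_real_, is_combination = TRUE))
  }
  out
}

#' @rdname tidy.mrs_fit
#' @export
glance.mrs_fit <- function(x, ...) {
  tibble::tibble(
    n_points = length(x$y), n_components = length(x$amplitudes),
    rms_residual = sqrt(mean(x$residual^2)),
    phase0 = x$phase0, global_broadening = x$global_broadening,
    alpha_B = x$alpha_B_used, alpha_S = x$alpha_S_used,
    noise_sd = x$noise_sd, condition_number = x$condition_number,
    converged = x$convergence == 0)
}

#' Plot a fit in the conventional stacked layout
#'
#' Data, fitted curve, baseline and residual against chemical shift.
#'
#' @param object An `mrs_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mrs_fit <- function(object, ...) {
  offset <- 1.1 * diff(range(object$y))
  d <- tibble::tibble(
    ppm = rep(object$ppm, 4),
    value = c(object$y, object$fitted, object$baseline,
              object$residual + offset),
    trace = rep(c("data", "fit", "baseline", "residual"),
                each = length(object$ppm)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ppm, y = .data$value,
                                  colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Chemical shift (ppm)", y = "Intensity (a.u.)",
                  colour = NULL)
}
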
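#' Frequency-domain MRS spectrum
#'
#' A complex spectrum sampled on an [acq_grid()], the unit every pipeline
#' stage consumes. Spectra are stored in the frequency domain; conversion
#' to and from the time-domain FID is available through [spec_fid()] /
#' [fid_spec()].
#'
#' @param signal Complex (or numeric) vector of length `grid$n_points`.
#' @param grid An [acq_grid()].
#' @param meta Named list of free-form acquisition metadata (TE, TR, ...).
#' @return An object of class `mrs_spectrum`.
#' @export
mrs_spectrum <- function(signal, grid, meta = list()) {
  stopifnot(inherits(grid, "acq_grid"))
  if (length(signal) != grid$n_points) {
    abort("`signal` length must equal `grid$n_points`.")
  }
  if (!all(is.finite(Re(signal))) || !all(is.finite(Im(signal)))) {
    abort("`signal` must be finite.")
  }
  structure(list(signal = as.complex(signal), grid = grid, meta = meta),
            class = "mrs_spectrum")
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("<mrs_spectrum> %d points on %.0f Hz / %.2f MHz grid\n",
              x$grid$n_points, x$grid$bandwidth, x$grid$transmitter_freq))
  invisible(x)
}

#' @export
length.mrs_spectrum <- function(x) length(x$signal)

#' Tidy a spectrum into a tibble
#'
#' One row per grid point with columns `ppm`, `hz`, `real`, `imag`.
#'
#' @param x An `mrs_spectrum`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mrs_spectrum <- function(x, ...) {
  tibble::tibble(ppm = ppm_axis(x$grid), hz = hz_axis(x$grid),
                 real = Re(x$signal), imag = Im(x$signal))
}

#' @export
as.data.frame.mrs_spectrum <- function(x, ...) as.data.frame(tidy(x))

#' Plot a spectrum
#'
#' Real part against chemical shift, with the ppm axis reversed as is
#' conventional in NMR display.
#'
#' @param object An `mrs_spectrum`.
#' @param xlim ppm window to display (length-2, low then high).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mrs_spectrum <- function(object, xlim = c(0, 4.5), ...) {
  d <- tidy(object)
  d <- d[d$ppm >= min(xlim) & d$ppm <= max(xlim), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ppm, y = .data$real)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Chemical shift (ppm)", y = "Intensity (a.u.)")
}

# -- time/frequency conversion ------------------------------------------------

# Our spectrum lives on an fftshifted axis (carrier at the center). The FID
# is indexed by t = (0:(n-1)) / bandwidth seconds.
#' Convert a frequency-domain signal to a time-domain FID and back
#'
#' Used internally to apply exact frequency shifts and Lorentzian
#' broadening as time-domain multiplications.
#'
#' @param signal Complex vector on the (ascending, carrier-centered)
#'   frequency axis of `grid`.
#' @param grid An [acq_grid()].
#' @return Complex vector.
#' @keywords internal
#' @export
spec_fid <- function(signal, grid) {
  n <- grid$n_points
  # undo fftshift, inverse transform
  fft(c(signal[(n / 2 + 1):n], signal[1:(n / 2)]), inverse = TRUE) / n
}

#' @rdname spec_fid
#' @export
fid_spec <- function(fid, grid) {
  n <- grid$n_points
  s <- fft(fid)
  c(s[(n / 2 + 1):n], s[1:(n / 2)])
}

fid_time <- function(grid) (seq_len(grid$n_points) - 1L) / grid$bandwidth

# Apply zero-order phase (rad), global Lorentzian broadening (Hz, FWHM
# added), and a frequency shift (Hz) to a frequency-domain signal.
transform_signal <- function(signal, grid, phase0 = 0, broaden_hz = 0,
                             shift_hz = 0) {
  out <- signal
  if (broaden_hz != 0 || shift_hz != 0) {
    t <- fid_time(grid)
    # decay acts on |t| of the circular time axis (second half of the DFT
    # array is negative time); the shift theorem uses the plain axis
    tw <- pmin(t, grid$n_points / grid$bandwidth - t)
    fid <- spec_fid(out, grid)
    fid <- fid * exp(-pi * broaden_hz * tw) * exp(2i * pi * shift_hz * t)
    out <- fid_spec(fid, grid)
  }
  if (phase0 != 0) out <- out * exp(1i * phase0)
  out
}

# Integrated real-part area in intensity * Hz units.
spec_area <- function(signal, grid) {
  sum(Re(signal)) * grid$bandwidth / grid$n_points
}
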
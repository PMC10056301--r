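#' Acquisition grid for a spectroscopy session
#'
#' Defines the shared frequency axis every spectrum and basis component in a
#' session lives on: number of complex points, spectral bandwidth, the
#' transmitter (Larmor) frequency that converts Hz to ppm, and the chemical
#' shift assigned to the carrier. Defaults match a typical 3 T single-voxel
#' PRESS acquisition (2048 points, 2000 Hz bandwidth).
#'
#' The frequency axis is stored ascending in both Hz and ppm; conventional
#' MRS display (ppm decreasing left to right) is applied only by the plot
#' methods.
#'
#' @param n_points Number of complex points (>= 64).
#' @param bandwidth Spectral width in Hz.
#' @param transmitter_freq Transmitter frequency in MHz; 127.74 MHz for
#'   protons at 3 T. One ppm equals `transmitter_freq` Hz.
#' @param ppm_reference Chemical shift (ppm) assigned to the carrier
#'   (center of the spectral window); 4.7 ppm places the water resonance
#'   near the center.
#' @return An object of class `acq_grid`.
#' @examples
#' g <- acq_grid()
#' range(ppm_axis(g))
#' @export
acq_grid <- function(n_points = 2048L, bandwidth = 2000,
                     transmitter_freq = 127.74, ppm_reference = 4.7) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 64) {
    abort("`n_points` must be a single number >= 64.")
  }
  stopifnot_scalar_pos(bandwidth, "bandwidth")
  stopifnot_scalar_pos(transmitter_freq, "transmitter_freq")
  structure(
    list(n_points = as.integer(n_points), bandwidth = bandwidth,
         transmitter_freq = transmitter_freq, ppm_reference = ppm_reference),
    class = "acq_grid"
  )
}

#' @export
print.acq_grid <- function(x, ...) {
  cat(sprintf(
    "<acq_grid> %d points, %.0f Hz bandwidth, %.2f MHz, carrier at %.2f ppm\n",
    x$n_points, x$bandwidth, x$transmitter_freq, x$ppm_reference))
  cat(sprintf("  ppm range: %.2f .. %.2f\n", min(ppm_axis(x)), max(ppm_axis(x))))
  invisible(x)
}

#' Frequency axes of an acquisition grid
#'
#' `hz_axis()` returns the frequency offset from the carrier in Hz
#' (ascending, spanning `[-bw/2, bw/2)`); `ppm_axis()` the corresponding
#' chemical-shift axis. The two are related by
#' `ppm = ppm_reference + hz / transmitter_freq`, a bijection on the grid.
#'
#' @param grid An [acq_grid()].
#' @return Numeric vector of length `n_points`.
#' @export
hz_axis <- function(grid) {
  stopifnot(inherits(grid, "acq_grid"))
  df <- grid$bandwidth / grid$n_points
  seq(-grid$bandwidth / 2, by = df, length.out = grid$n_points)
}

#' @rdname hz_axis
#' @export
ppm_axis <- function(grid) {
  grid$ppm_reference + hz_axis(grid) / grid$transmitter_freq
}

#' Convert between ppm and Hz offsets on a grid
#'
#' @param grid An [acq_grid()].
#' @param ppm,hz Values to convert.
#' @return Numeric vector.
#' @export
ppm_to_hz <- function(ppm, grid) (ppm - grid$ppm_reference) * grid$transmitter_freq

#' @rdname ppm_to_hz
#' @export
hz_to_ppm <- function(hz, grid) grid$ppm_reference + hz / grid$transmitter_freq

same_grid <- function(a, b, tol = 1e-9) {
  a$n_points == b$n_points &&
    abs(a$bandwidth - b$bandwidth) < tol &&
    abs(a$transmitter_freq - b$transmitter_freq) < tol &&
    abs(a$ppm_reference - b$ppm_reference) < tol
}

ppm_window <- function(grid, lo, hi) {
  ppm <- ppm_axis(grid)
  which(ppm >= lo & ppm <= hi)
}
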
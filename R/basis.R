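#' Basis component and basis set containers
#'
#' A `basis_component` is one named reference spectrum (metabolite or
#' macromolecule/lipid) on an acquisition grid; its real-part area per unit
#' concentration equals `protons_at_reference` (the N1H count entering
#' water scaling). A `basis_set` is a list of components sharing one grid,
#' plus the combination rules (tCho = PCh + GPC, tNA = NAA + NAAG,
#' tCr = Cr + PCr, Glx = Glu + Gln, and the macromolecule/lipid sums) used
#' when reporting combined resonances.
#'
#' @param name Component label.
#' @param signal Complex spectrum on `grid` (area scaled per 1 mM).
#' @param grid An [acq_grid()].
#' @param protons_at_reference Proton count contributing to the modeled
#'   resonances (N1H of the water-scaling equation).
#' @param is_macromolecule Flag for broad background components.
#' @return `basis_component` / `basis_set` objects.
#' @export
basis_component <- function(name, signal, grid, protons_at_reference,
                            is_macromolecule = FALSE) {
  stopifnot_scalar_pos(protons_at_reference, "protons_at_reference")
  sp <- mrs_spectrum(signal, grid)
  structure(list(name = name, spectrum = sp, grid = grid,
                 protons_at_reference = protons_at_reference,
                 is_macromolecule = isTRUE(is_macromolecule)),
            class = "basis_component")
}

#' @param components List of `basis_component`s on a common grid.
#' @param combinations Named list mapping a combined name to member
#'   component names; defaults to [default_combinations()] filtered to the
#'   members present.
#' @rdname basis_component
#' @export
basis_set <- function(components, combinations = NULL) {
  nm <- vapply(components, function(x) x$name, character(1))
  if (anyDuplicated(nm)) abort("Component names must be unique.")
  g <- components[[1]]$grid
  for (cmp in components) {
    if (!same_grid(cmp$grid, g)) abort("All components must share one grid.")
  }
  if (is.null(combinations)) {
    combinations <- Filter(function(m) all(m %in% nm), default_combinations())
  } else {
    for (m in combinations) {
      if (!all(m %in% nm)) abort("Combination members must exist in the basis.")
    }
  }
  names(components) <- nm
  structure(list(components = components, combinations = combinations,
                 grid = g), class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> %d components: %s\n", length(x$components),
              paste(names(x$components), collapse = ", ")))
  invisible(x)
}

#' @export
length.basis_set <- function(x) length(x$components)

#' Standard combination rules for reported metabolite sums
#'
#' @return Named list of member component names.
#' @export
default_combinations <- function() {
  list(
    tCho = c("PCh", "GPC"),
    tNA  = c("NAA", "NAAG"),
    tCr  = c("Cr", "PCr"),
    Glx  = c("Glu", "Gln"),
    `Lip13a+Lip13b` = c("Lip13a", "Lip13b"),
    `MM14+Lip13a+Lip13b+MM12` = c("MM14", "Lip13a", "Lip13b", "MM12"),
    `MM09+Lip09` = c("MM09", "Lip09"),
    `MM20+Lip20` = c("MM20", "Lip20")
  )
}

# -- lineshapes ---------------------------------------------------------------

# Complex Lorentzian of unit area (absorption real part), FWHM fwhm_hz.
lorentz_line <- function(hz, center_hz, fwhm_hz, area = 1) {
  area * (2 / (pi * fwhm_hz)) / (1 + 2i * (hz - center_hz) / fwhm_hz)
}

gauss_line <- function(hz, center_hz, fwhm_hz, area = 1) {
  sigma <- fwhm_hz / (2 * sqrt(2 * log(2)))
  area / (sigma * sqrt(2 * pi)) * exp(-(hz - center_hz)^2 / (2 * sigma^2))
}

#' Synthesize one basis component from a multiplet line list
#'
#' Builds a complex spectrum as a sum of Lorentzian lines at the stated
#' chemical shifts with areas proportional to `relative_amplitude`, so the
#' total real-part area per unit concentration equals the component's
#' proton count. Optionally adds the chemical-referencing lines used in
#' phantom basis acquisitions: DSS at 0 ppm and formate at 8.4 ppm.
#'
#' @param lines Data frame with columns `center_ppm` and
#'   `relative_amplitude` (protons contributing at each position).
#' @param linewidth Lorentzian FWHM in Hz (> 0) applied to every line.
#' @param grid An [acq_grid()].
#' @param name Component label.
#' @param protons N1H proton count for water scaling; defaults to the sum
#'   of relative amplitudes.
#' @param include_reference Add DSS (0 ppm, area 9) and formate (8.4 ppm,
#'   area 1) reference lines.
#' @param is_macromolecule Flag passed through to the component.
#' @return A [basis_component()].
#' @examples
#' g <- acq_grid()
#' naa <- make_basis_component(
#'   data.frame(center_ppm = 2.01, relative_amplitude = 3),
#'   linewidth = 3, grid = g, name = "NAA")
#' @export
make_basis_component <- function(lines, linewidth, grid, name = "component",
                                 protons = NULL, include_reference = FALSE,
                                 is_macromolecule = FALSE) {
  stopifnot_scalar_pos(linewidth, "linewidth")
  stopifnot(is.data.frame(lines),
            all(c("center_ppm", "relative_amplitude") %in% names(lines)))
  if (any(lines$relative_amplitude < 0)) {
    abort("`relative_amplitude` must be >= 0.")
  }
  ppm <- ppm_axis(grid)
  if (any(lines$center_ppm < min(ppm) | lines$center_ppm > max(ppm))) {
    abort("Line center outside the ppm range of the grid.")
  }
  hz <- hz_axis(grid)
  sig <- complex(grid$n_points)
  for (i in seq_len(nrow(lines))) {
    sig <- sig + lorentz_line(hz, ppm_to_hz(lines$center_ppm[i], grid),
                              linewidth, area = lines$relative_amplitude[i])
  }
  if (include_reference) {
    sig <- sig + lorentz_line(hz, ppm_to_hz(0, grid), linewidth, area = 9) +
      lorentz_line(hz, ppm_to_hz(8.4, grid), linewidth, area = 1)
  }
  if (is.null(protons)) protons <- sum(lines$relative_amplitude)
  basis_component(name, sig, grid, protons, is_macromolecule)
}

# -- shipped line tables ------------------------------------------------------

#' Shipped chemical-shift tables
#'
#' `metabolite_line_table()` returns the simplified first-order multiplet
#' table (one row per line: metabolite, center ppm, relative amplitude in
#' protons) for the 16 brain metabolites plus choline;
#' `mm_line_table()` the macromolecule/lipid single-Gaussian table.
#'
#' @return A tibble.
#' @export
metabolite_line_table <- function() {
  path <- system.file("extdata", "metabolite_lines.csv", package = "mrsquant")
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' @rdname metabolite_line_table
#' @export
mm_line_table <- function() {
  path <- system.file("extdata", "mm_lines.csv", package = "mrsquant")
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' Construct the standard basis sets
#'
#' `brain_basis()` builds the 16-metabolite basis (optionally with the nine
#' macromolecule/lipid Gaussians); `phantom_basis()` builds the six
#' components of the standard GE MRS phantom (NAA, Cr, Cho, Glu, Ins, Lac).
#'
#' @param grid An [acq_grid()].
#' @param linewidth Lorentzian FWHM in Hz for the metabolite lines.
#' @param include_mm Include the macromolecule/lipid components.
#' @param metabolites Character vector of metabolites to include.
#' @return A [basis_set()].
#' @export
brain_basis <- function(grid = acq_grid(), linewidth = 4,
                        include_mm = TRUE,
                        metabolites = c("Ala", "Asp", "Cr", "PCr", "GABA",
                                        "Glc", "Gln", "Glu", "GSH", "GPC",
                                        "PCh", "Ins", "Lac", "NAA", "NAAG",
                                        "Tau")) {
  tab <- metabolite_line_table()
  comps <- lapply(metabolites, function(m) {
    make_basis_component(tab[tab$metabolite == m, ], linewidth, grid, name = m)
  })
  if (include_mm) {
    mm <- mm_line_table()
    hz <- hz_axis(grid)
    comps <- c(comps, lapply(seq_len(nrow(mm)), function(i) {
      sig <- gauss_line(hz, ppm_to_hz(mm$center_ppm[i], grid),
                        mm$fwhm_ppm[i] * grid$transmitter_freq, area = 1)
      basis_component(mm$name[i], complex(real = sig,
                                          imaginary = numeric(length(sig))),
                      grid, protons_at_reference = 1, is_macromolecule = TRUE)
    }))
  }
  basis_set(comps)
}

#' @rdname brain_basis
#' @export
phantom_basis <- function(grid = acq_grid(), linewidth = 3) {
  tab <- metabolite_line_table()
  comps <- lapply(c("NAA", "Cr", "Cho", "Glu", "Ins", "Lac"), function(m) {
    make_basis_component(tab[tab$metabolite == m, ], linewidth, grid, name = m)
  })
  basis_set(comps, combinations = list())
}
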
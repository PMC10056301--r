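#' Write and read spectra as JSON
#'
#' Spectra are interchanged as a documented JSON schema: the grid
#' metadata, free-form acquisition metadata, and the complex signal as
#' parallel real/imaginary arrays. When a [ground_truth()] is supplied it
#' is serialized as a `<path>.truth.json` sidecar and transparently
#' reloaded by `read_spectrum()`.
#'
#' @param spec An `mrs_spectrum`.
#' @param path Output path.
#' @param truth Optional [ground_truth()] sidecar.
#' @return `write_spectrum()` returns `path` invisibly; `read_spectrum()`
#'   an `mrs_spectrum` (with attribute `"truth"` when a sidecar exists).
#' @export
write_spectrum <- function(spec, path, truth = NULL) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  obj <- list(format = "mrsquant-spectrum-v1",
              grid = unclass(spec$grid), meta = spec$meta,
              real = Re(spec$signal), imag = Im(spec$signal))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(concentrations = as.list(truth$concentrations),
           baseline_coefficients = truth$baseline_coefficients,
           noise_sd = truth$noise_sd,
           water_amplitude = truth$water_amplitude,
           phase0 = truth$phase0, seed = truth$seed),
      paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$grid)) abort("Missing grid metadata in spectrum file.")
  g <- obj$grid
  grid <- acq_grid(g$n_points, g$bandwidth, g$transmitter_freq,
                   g$ppm_reference)
  spec <- mrs_spectrum(complex(real = obj$real, imaginary = obj$imag), grid,
                       meta = as.list(obj$meta))
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar)) {
    tr <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(spec, "truth") <- ground_truth(
      unlist(tr$concentrations),
      baseline_coefficients = tr$baseline_coefficients %||% numeric(),
      noise_sd = tr$noise_sd %||% 0,
      water_amplitude = tr$water_amplitude %||% 0,
      phase0 = tr$phase0 %||% 0, seed = tr$seed)
  }
  spec
}

#' Write and read basis sets in a plain-text dialect
#'
#' A fixed-layout text format modeled on conventional linear-combination
#' basis files: a key-value header block (sequence name, TE, TR,
#' bandwidth, point count, transmitter frequency, carrier ppm), then one
#' block per component with its name, proton count and macromolecule
#' flag, followed by the complex spectrum as interleaved real/imaginary
#' value pairs, four pairs per line. Round trips preserve metadata
#' exactly and spectra to better than 1e-6 relative.
#'
#' @param basis A [basis_set()].
#' @param path File path.
#' @param te_ms,tr_ms,sequence Header metadata (echo time, repetition
#'   time, sequence name).
#' @return `write_basis()` returns `path` invisibly; `read_basis()` a
#'   [basis_set()] (header in attribute `"header"`).
#' @export
write_basis <- function(basis, path, te_ms = 35, tr_ms = 10000,
                        sequence = "PRESS") {
  stopifnot(inherits(basis, "basis_set"))
  g <- basis$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "$MRSQUANT_BASIS version=1",
    sprintf("sequence: %s", sequence),
    sprintf("te_ms: %g", te_ms),
    sprintf("tr_ms: %g", tr_ms),
    sprintf("bandwidth_hz: %.10g", g$bandwidth),
    sprintf("n_points: %d", g$n_points),
    sprintf("transmitter_mhz: %.10g", g$transmitter_freq),
    sprintf("ppm_reference: %.10g", g$ppm_reference),
    sprintf("n_components: %d", length(basis$components))), con)
  for (cmp in basis$components) {
    writeLines(sprintf("$COMPONENT name=%s protons=%.10g is_mm=%d",
                       cmp$name, cmp$protons_at_reference,
                       as.integer(cmp$is_macromolecule)), con)
    v <- as.vector(rbind(Re(cmp$spectrum$signal), Im(cmp$spectrum$signal)))
    lines <- split(v, ceiling(seq_along(v) / 8))
    writeLines(vapply(lines, function(x) {
      paste(sprintf("% .9e", x), collapse = " ")
    }, character(1)), con)
  }
  writeLines("$END", con)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "$MRSQUANT_BASIS")) {
    abort("Not a basis file (line 1: missing $MRSQUANT_BASIS marker).")
  }
  if (lines[length(lines)] != "$END") {
    abort("Truncated basis file: missing $END marker.")
  }
  header <- list()
  i <- 2L
  while (i <= length(lines) && !startsWith(lines[i], "$COMPONENT")) {
    kv <- strsplit(lines[i], ":\\s*")[[1]]
    if (length(kv) != 2) abort(sprintf("Malformed header at line %d.", i))
    header[[kv[1]]] <- kv[2]
    i <- i + 1L
  }
  need <- c("bandwidth_hz", "n_points", "transmitter_mhz", "ppm_reference",
            "n_components")
  if (!all(need %in% names(header))) {
    abort(sprintf("Header missing field(s): %s",
                  paste(setdiff(need, names(header)), collapse = ", ")))
  }
  grid <- acq_grid(as.integer(header$n_points),
                   as.numeric(header$bandwidth_hz),
                   as.numeric(header$transmitter_mhz),
                   as.numeric(header$ppm_reference))
  n <- grid$n_points
  comps <- list()
  while (i <= length(lines) && startsWith(lines[i], "$COMPONENT")) {
    m <- regmatches(lines[i],
                    regexec("name=(\\S+) protons=(\\S+) is_mm=(\\d)",
                            lines[i]))[[1]]
    if (length(m) != 4) abort(sprintf("Malformed component header, line %d.", i))
    i <- i + 1L
    vals <- numeric(0)
    while (i <= length(lines) && !startsWith(lines[i], "$")) {
      vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      i <- i + 1L
    }
    if (length(vals) != 2 * n) {
      abort(sprintf("Component %s: expected %d values, got %d (near line %d).",
                    m[2], 2 * n, length(vals), i))
    }
    sig <- complex(real = vals[c(TRUE, FALSE)], imaginary = vals[c(FALSE, TRUE)])
    comps[[length(comps) + 1L]] <-
      basis_component(m[2], sig, grid, as.numeric(m[3]), m[4] == "1")
  }
  if (length(comps) != as.integer(header$n_components)) {
    abort("Component count does not match header.")
  }
  out <- basis_set(comps)
  attr(out, "header") <- header
  out
}
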
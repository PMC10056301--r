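# Shared fixtures, built in code. The default grid matches the 3 T
# acquisition (2048 points, 2000 Hz); the small bases keep fits fast.

test_grid <- acq_grid()

single_line_basis <- function(metabolite = "NAA", linewidth = 3,
                              grid = test_grid) {
  tab <- metabolite_line_table()
  basis_set(list(make_basis_component(tab[tab$metabolite == metabolite, ],
                                      linewidth, grid, name = metabolite)),
            combinations = list())
}

three_component_basis <- function(grid = test_grid, linewidth = 3) {
  tab <- metabolite_line_table()
  mk <- function(m) make_basis_component(tab[tab$metabolite == m, ],
                                         linewidth, grid, name = m)
  basis_set(list(mk("NAA"), mk("Cr"), mk("Ins")), combinations = list())
}

# linear-model-only configuration: no nuisance search, no baseline penalty
# selection; used where an analytic oracle describes plain least squares
ls_config <- function(...) {
  fit_config(max_shift = 0, max_broadening = 0, n_starts = 1L,
             alpha_B = 0, ...)
}

fast_config <- function(...) {
  fit_config(max_shift = 0, n_starts = 2L, ...)
}

# brute-force between-class-variance maximizer over histogram-bin
# boundaries; deliberately naive, kept independent of otsu_threshold()
otsu_brute_force <- function(x, n_bins = 256L) {
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  xb <- mids[bin]  # class means from bin midpoints, as the histogram does
  v <- vapply(seq_len(n_bins - 1L), function(k) {
    lo <- bin <= k
    if (!any(lo) || all(lo)) return(-Inf)
    mean(lo) * (1 - mean(lo)) * (mean(xb[lo]) - mean(xb[!lo]))^2
  }, numeric(1))
  best <- which(v >= max(v) - 1e-12 * abs(max(v)))
  mean(breaks[best + 1L])
}
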
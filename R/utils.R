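#' @importFrom rlang abort warn .data
#' @importFrom stats coef fft lm mad optim pt qt sd shapiro.test t.test
#'   wilcox.test cor cor.test nlminb rnorm runif setNames var
#' @importFrom utils head tail
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

# Complex circular Gaussian noise: independent N(0, sd) real and imaginary.
complex_noise <- function(n, sd) {
  complex(real = rnorm(n, sd = sd), imaginary = rnorm(n, sd = sd))
}
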
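# internal helpers shared across modules

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded routines do not
#' perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# stationary AR(1) noise with a given marginal standard deviation;
# phi = 0 gives white noise, sd_marg = 0 gives exact zeros
ar1_noise <- function(n, phi = 0, sd_marg = 1) {
  stopifnot(n >= 1, abs(phi) < 1, sd_marg >= 0)
  if (sd_marg == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd_marg * sqrt(1 - phi^2))
  x0 <- stats::rnorm(1, 0, sd_marg)
  as.numeric(stats::filter(innov, phi, method = "recursive", init = x0))
}

# derive a reproducible sub-seed (kept below 2^31) from a base seed
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a
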
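#' Evaluate code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state on exit, so seeded helpers do not perturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Cheap integer mixing (multiplicative congruential step) keeping results in
#' the positive 32-bit range so they are valid `set.seed()` inputs.
#'
#' @param seed master integer seed.
#' @param ... additional integer offsets (e.g. subject index, fold index).
#' @return a single integer in \[1, 2^31 - 2\].
#' @keywords internal
derive_seed <- function(seed, ...) {
  m <- 2147483647
  x <- as.double(seed) %% m
  for (k in c(...)) {
    x <- (x * 48271 + as.double(k) + 1) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

# stop() with sprintf formatting and no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
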
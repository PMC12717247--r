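#' Derive a child seed from a master seed
#'
#' Counter-based seed expansion: every source of randomness in a pipeline run
#' draws its own child seed from the single master seed so that stages are
#' individually reproducible. Uses two multiplicative-congruential steps over
#' the Mersenne prime 2^31 - 1; all arithmetic stays exact in doubles.
#'
#' @param master integer master seed.
#' @param index integer counter (scalar or vector) identifying the consumer.
#' @return integer seed(s) in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L, is.numeric(index))
  m <- 2147483647
  a <- (abs(master) %% m)
  s <- (a * 48271) %% m
  s <- (s + (abs(index) %% m) * 104729) %% m
  s <- (s * 16807) %% m
  as.integer(s %% (m - 2) + 1)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the R random number generator, evaluates `expr`, and restores the
#' previous RNG state, so seeded helpers never perturb the caller's
#' random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Round half away from zero
#'
#' Deterministic rounding used for fraction-of-count rules (base `round()`
#' rounds half to even).
#'
#' @param x numeric vector.
#' @return rounded values.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ms <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
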
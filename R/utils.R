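# Internal helpers: seeded evaluation and deterministic seed derivation.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the caller's
#' RNG state afterwards, so seeded operations do not perturb surrounding code.
#' If `seed` is `NULL` the expression runs on the ambient RNG stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and integer keys
#'
#' Deterministic mixing of a master seed with one or more non-negative integer
#' keys (replicate index, scenario indices, a strategy code ...). Uses a
#' multiply-add chain modulo 2^31 - 1, exact in double precision, so derived
#' seeds are reproducible across platforms and always valid R integers.
#'
#' @param master integer master seed.
#' @param ... non-negative integer keys, applied in order.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 3, 1)
derive_seed <- function(master, ...) {
  keys <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.numeric(master) %% m
  for (k in c(keys, 0)) {
    # 69069 * (m - 1) < 2^53: exact in doubles
    s <- (s * 69069 + as.numeric(k) + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# Stop with a formatted message.
fail <- function(...) stop(sprintf(...), call. = FALSE)

# Sample variance with the n - 1 denominator (explicit alias for clarity).
sample_var <- function(x) stats::var(x)

# Check a dosage matrix only contains 0/1/2.
check_dosages <- function(x) {
  if (!all(x %in% c(0, 1, 2)))
    fail("genotype dosages must be 0, 1 or 2; found values outside {0,1,2}")
  invisible(TRUE)
}
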
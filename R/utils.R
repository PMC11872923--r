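# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps every generator a pure function of (params, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
  }
  force(expr)
}

# Derive a stream-specific child seed from a base seed; stays below 2^31.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 69069 + 12345 * as.numeric(k)) %% 2147483647
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("'%s' must be a finite number in [%g, %g]", name, lower, upper)
  invisible(x)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))
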
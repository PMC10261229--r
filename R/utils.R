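# Internal helpers: classed errors, seeded evaluation, argument checks.

pg_stop <- function(subclass, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(subclass, "petgate_error"), call = call))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    pg_stop("petgate_invalid_parameter",
            sprintf("`%s` must be a single finite number", name))
  bad_lo <- if (strict_lower) x <= lower else x < lower
  bad_hi <- if (strict_upper) x >= upper else x > upper
  if (bad_lo || bad_hi)
    pg_stop("petgate_invalid_parameter",
            sprintf("`%s` = %g is outside its allowed range", name, x))
  invisible(x)
}

# Evaluate `code` with a fixed RNG state, restoring the caller's stream.
with_rng_seed <- function(seed, code) {
  if (!is.null(seed)) {
    check_scalar_number(seed, "seed")
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible 31-bit sub-seed from a base seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}
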
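#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic fan-out of a global seed to per-stage seeds; kept well
# below .Machine$integer.max so downstream set.seed() never overflows.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + as.numeric(stage) * 1000003) %% 2147483587L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower)
    stopf("'%s' must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stopf("'%s' must be >= %g (got %g)", name, lower, x)
  if (x > upper) stopf("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}
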
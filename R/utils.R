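# internal helpers: argument checking, seeded evaluation, substream seeds

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stopf("'%s' must be supplied", name)
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single non-missing number", name)
  if (integer && x != round(x))
    stopf("'%s' must be an integer, got %s", name, format(x))
  if (x < lower || x > upper)
    stopf("'%s' must be in [%s, %s], got %s", name,
          format(lower), format(upper), format(x))
  invisible(x)
}

check_fraction <- function(x, name, open_upper = FALSE) {
  check_number(x, name, lower = 0, upper = 1)
  if (open_upper && x >= 1) stopf("'%s' must be < 1, got %s", name, format(x))
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_number(seed, "seed", integer = TRUE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive n reproducible sub-seeds (< 2^31) from a root seed, for per-replicate
# RNG substreams. NULL root gives NULL sub-seeds (free-running RNG).
substream_seeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  as.list(with_seed(seed, sample.int(.Machine$integer.max, n)))
}

# intercept + optional covariates as an n-row design matrix
design_matrix <- function(n, covariates = NULL) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  X <- cbind(1, as.matrix(covariates))
  if (nrow(X) != n) stopf("covariates must have %d rows", n)
  X
}
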
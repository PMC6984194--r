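# Internal helpers shared across modules.

abort_validation <- function(msg, ...) {
  abort(msg, class = "smrbci_validation_error", ...)
}

abort_numerical <- function(msg, ...) {
  abort(msg, class = "smrbci_numerical_error", ...)
}

# Check a scalar numeric field, raising a validation error that names the field.
check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         allow_null = FALSE, integerish = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort_validation(sprintf("field `%s` must not be NULL", field))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(sprintf("field `%s` must be a finite numeric scalar", field))
  }
  if (x < lower || x > upper) {
    abort_validation(sprintf("field `%s` must be in [%s, %s] (got %s)",
                             field, format(lower), format(upper), format(x)))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort_validation(sprintf("field `%s` must be a whole number", field))
  }
  invisible(x)
}

check_probability <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort_validation(sprintf("`%s` must contain probabilities in [0, 1]", field))
  }
  invisible(x)
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded package functions do not disturb user scripts.
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  check_scalar(seed, "seed", integerish = TRUE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a master seed, kept below 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1103L + as.integer(k) * 12347L) %% 2147483587L
}

# Symmetric inverse square root via eigendecomposition.
sym_inv_sqrt <- function(m, tol = 1e-12) {
  e <- eigen(m, symmetric = TRUE)
  vals <- e$values
  if (any(vals < tol * max(vals))) {
    abort_numerical(paste0(
      "covariance matrix is rank deficient; ",
      "apply shrinkage (e.g. fit_csp(..., shrinkage = 0.05))"))
  }
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}
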
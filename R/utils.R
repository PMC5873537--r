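# Internal helpers shared across modules.

# Days-to-months conversion used when visit schedules are generated in days
# but models measure time in months.
DAYS_PER_MONTH_FACTOR <- 12 / 365.25

abort_structure <- function(msg) abort(msg, class = "loda_error_structure")
abort_numeric <- function(msg) abort(msg, class = "loda_error_numeric")
abort_argument <- function(msg) abort(msg, class = "loda_error_argument")
abort_config <- function(msg) abort(msg, class = "loda_error_config")
abort_degenerate <- function(msg) abort(msg, class = "loda_error_degenerate")
abort_convergence <- function(msg, last = NULL) {
  abort(msg, class = "loda_error_convergence", last_iterate = last)
}

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
# With seed = NULL the global stream is used (and advanced).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive `n` child seeds from a master seed, reproducibly and independently
# of the caller's RNG state. Kept below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Log density of a multivariate normal via Cholesky factorisation.
mvn_log_density <- function(x, mean, cov) {
  ch <- tryCatch(chol(cov), error = function(e) {
    abort_structure("covariance matrix is not positive definite")
  })
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# One multivariate normal draw (uses the current RNG stream).
rmvn1 <- function(mean, cov) {
  ch <- chol(cov)
  drop(mean + crossprod(ch, rnorm(length(mean))))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
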
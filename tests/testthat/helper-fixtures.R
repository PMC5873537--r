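# Shared fixtures: tiny model builders and cached heavy computations.

suppressPackageStartupMessages({
  library(dplyr)
})

# --- tiny all-gaussian toy (2 markers, random intercept + slope each) -----

toy_gauss_specs <- function() {
  marker_specs(
    marker_spec("a", "gaussian"),
    marker_spec("b", "gaussian")
  )
}

toy_gauss_params <- function(sig_a = 0.3, sig_b = 0.4) {
  sds <- c("a:int" = 0.4, "a:slope" = 0.05, "b:int" = 0.6, "b:slope" = 0.08)
  corr <- data.frame(a = c("a:int", "a:int", "a:slope"),
                     b = c("a:slope", "b:int", "b:slope"),
                     corr = c(-0.3, 0.4, 0.2))
  D <- assemble_covariance(sds, corr)
  group_parameters(toy_gauss_specs(), mu = c(2, -0.1, 1, 0.05), D = D,
                   sigma = c(a = sig_a, b = sig_b))
}

# long-format data for one patient on the toy model
toy_gauss_patient <- function(values_a = c(2.1, 1.9), values_b = c(1.2, 0.8),
                              times = c(0, 6), id = "p1", group = NA_integer_) {
  bind_rows(
    tibble::tibble(patient_id = id, group = group, marker = "a",
                   time_months = times, value = values_a),
    tibble::tibble(patient_id = id, group = group, marker = "b",
                   time_months = times, value = values_b)
  )
}

# a single-marker, random-intercept-only gaussian model (scalar algebra)
scalar_specs <- function() marker_specs(marker_spec("y", "gaussian", random_slope = FALSE))
scalar_params <- function(mu = 1.5, d = 0.5, sigma = 0.7) {
  group_parameters(scalar_specs(), mu = mu, D = matrix(d, 1, 1),
                   sigma = c(y = sigma))
}
scalar_patient <- function(y, t = seq(0, by = 3, length.out = length(y)), id = "p1") {
  tibble::tibble(patient_id = id, group = NA_integer_, marker = "y",
                 time_months = t, value = y)
}

# mixed-family toy: gaussian + poisson + bernoulli(fixed slope)
toy_mixed_specs <- function() {
  marker_specs(
    marker_spec("g", "gaussian"),
    marker_spec("c", "poisson"),
    marker_spec("z", "bernoulli", random_slope = FALSE, fixed_slope = TRUE)
  )
}

toy_mixed_params <- function() {
  sds <- c("g:int" = 0.3, "g:slope" = 0.04, "c:int" = 0.35, "c:slope" = 0.02,
           "z:int" = 1.2)
  corr <- data.frame(a = c("g:int", "c:int"), b = c("c:int", "z:int"),
                     corr = c(0.3, -0.25))
  D <- assemble_covariance(sds, corr)
  group_parameters(toy_mixed_specs(),
                   mu = c(2, -0.05, 4.5, -0.01, -1.5), D = D,
                   sigma = c(g = 0.3), alpha = list(z = 0.02))
}

toy_mixed_patient <- function(id = "p1") {
  times <- c(0, 5, 11, 24)
  bind_rows(
    tibble::tibble(patient_id = id, group = NA_integer_, marker = "g",
                   time_months = times, value = c(2.2, 1.8, 2.0, 1.1)),
    tibble::tibble(patient_id = id, group = NA_integer_, marker = "c",
                   time_months = times, value = c(95, 88, 102, 80)),
    tibble::tibble(patient_id = id, group = NA_integer_, marker = "z",
                   time_months = times, value = c(0, 0, 1, 1))
  )
}

# a small two-group gaussian dataset for fast end-to-end fits
small_two_group_data <- function(n0 = 15, n1 = 15, seed = 99) {
  specs <- toy_gauss_specs()
  p0 <- toy_gauss_params()
  p1 <- group_parameters(specs, mu = c(1.2, 0.05, 1.8, -0.05),
                         D = params_D_test(p0), sigma = c(a = 0.3, b = 0.4))
  scn <- scenario_definition("toy", c(n0, n1),
                             list(c(150, 210), c(330, 400), c(700, 780)),
                             specs, list(p0, p1))
  simulate_dataset(scn, seed = seed)
}

params_D_test <- function(p) p$mixture$covariances[[1L]]
params_mu_test <- function(p) p$mixture$means[[1L]]

# plain-R multivariate normal log density (independent of package internals)
ref_dmvnorm <- function(x, mean, S) {
  q <- length(x)
  -0.5 * q * log(2 * pi) - 0.5 * determinant(S, logarithm = TRUE)$modulus[1] -
    0.5 * drop(t(x - mean) %*% solve(S) %*% (x - mean))
}

# --- cached heavy runs shared between acceptance criteria ----------------

.acceptance_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (!exists(key, envir = .acceptance_cache)) {
    assign(key, compute(), envir = .acceptance_cache)
  }
  get(key, envir = .acceptance_cache)
}

# Scenario 2 study: 10 replicates, fast profile, fit-once cross-validation.
# Serves accuracy, dispersion and gaussian-recovery checks.
scenario2_study <- function() {
  cache_get("scenario2_study", function() {
    run_study("scenario2", study_config(n_replicates = 10L, seed = 1L))
  })
}

# Scenario 1 group-0 recovery: 5 replicates, fits only.
scenario1_recovery <- function() {
  cache_get("scenario1_recovery", function() {
    run_study("scenario1",
              study_config(n_replicates = 5L, seed = 1L, fit_only = TRUE,
                           groups = 0L))
  })
}

# Scenario 1 accuracy: 5 replicates with subsampled prediction draws.
scenario1_study <- function() {
  cache_get("scenario1_study", function() {
    run_study("scenario1",
              study_config(n_replicates = 5L, seed = 1L,
                           prediction_draws = 100L, n_mc = 300L))
  })
}
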
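# Conditional, random-effects and marginal densities; random-effects
# estimation.

test_that("conditional log density matches hand-computed exponential-family terms", {
  # gaussian observation exactly at its conditional mean, sigma = 1
  sp <- marker_specs(marker_spec("y", "gaussian", random_slope = FALSE))
  pr <- group_parameters(sp, mu = 0, D = matrix(1, 1, 1), sigma = c(y = 1))
  d <- tibble::tibble(patient_id = "p", group = NA_integer_, marker = "y",
                      time_months = 0, value = 0.7)
  expect_equal(conditional_log_density(d, b = 0.7, pr), -0.5 * log(2 * pi))

  # bernoulli with linear predictor 0 and y = 1
  spb <- marker_specs(marker_spec("z", "bernoulli", random_slope = FALSE))
  prb <- group_parameters(spb, mu = 0, D = matrix(1, 1, 1))
  db <- tibble::tibble(patient_id = "p", group = NA_integer_, marker = "z",
                       time_months = 0, value = 1)
  expect_equal(conditional_log_density(db, b = 0, prb), log(0.5))

  # two markers, several observations: term-by-term oracle with explicit
  # density formulas
  pr2 <- toy_gauss_params()
  dat <- toy_gauss_patient(values_a = c(2.3, 1.7, 1.5), values_b = c(1.4, 0.9, 0.6),
                           times = c(0, 4, 9))
  b <- c(2.1, -0.12, 0.9, 0.06)
  expected <- 0
  for (i in 1:3) {
    t <- c(0, 4, 9)[i]
    eta_a <- b[1] + b[2] * t
    eta_b <- b[3] + b[4] * t
    ya <- c(2.3, 1.7, 1.5)[i]; yb <- c(1.4, 0.9, 0.6)[i]
    expected <- expected +
      (-0.5 * log(2 * pi * 0.3^2) - (ya - eta_a)^2 / (2 * 0.3^2)) +
      (-0.5 * log(2 * pi * 0.4^2) - (yb - eta_b)^2 / (2 * 0.4^2))
  }
  expect_equal(conditional_log_density(dat, b, pr2), expected)

  # poisson and bernoulli terms, against explicit formulas
  prm <- toy_mixed_params()
  dm <- toy_mixed_patient()
  bm <- c(2.0, -0.04, 4.4, -0.008, -1.2)
  tm <- c(0, 5, 11, 24)
  exp_g <- sum(-0.5 * log(2 * pi * 0.3^2) -
                 (c(2.2, 1.8, 2.0, 1.1) - (bm[1] + bm[2] * tm))^2 / (2 * 0.3^2))
  lam <- exp(bm[3] + bm[4] * tm)
  yc <- c(95, 88, 102, 80)
  exp_c <- sum(yc * log(lam) - lam - lfactorial(yc))
  eta_z <- bm[5] + 0.02 * tm
  yz <- c(0, 0, 1, 1)
  exp_z <- sum(yz * eta_z - log(1 + exp(eta_z)))
  expect_equal(conditional_log_density(dm, bm, prm), exp_g + exp_c + exp_z)
})

test_that("conditional log density validates dimensions", {
  pr <- toy_gauss_params()
  expect_error(conditional_log_density(toy_gauss_patient(), b = c(1, 2), pr),
               class = "loda_error_structure")
})

test_that("random-effects log density matches direct mixture evaluation", {
  q <- 3
  # K = 1 at the mode of the standard form
  mix1 <- re_mixture(1, rep(0, q), diag(q))
  expect_equal(random_effects_log_density(rep(0, q), mix1), -q / 2 * log(2 * pi))

  # degenerate two-component mixture equals its single component
  D <- diag(c(1, 2, 0.5))
  mix2 <- re_mixture(c(0.5, 0.5), list(1:3 * 1.0, 1:3 * 1.0), list(D, D))
  b <- c(0.4, 2.2, 2.8)
  expect_equal(random_effects_log_density(b, mix2),
               ref_dmvnorm(b, 1:3, D))

  # distinct components: direct two-term evaluation (mvtnorm as oracle)
  skip_if_not_installed("mvtnorm")
  m1 <- c(0, 0); m2 <- c(2, -1)
  D1 <- matrix(c(1, 0.3, 0.3, 0.8), 2); D2 <- diag(c(0.5, 1.5))
  mix <- re_mixture(c(0.3, 0.7), list(m1, m2), list(D1, D2))
  set.seed(1)
  for (i in 1:5) {
    b <- rnorm(2)
    direct <- log(0.3 * mvtnorm::dmvnorm(b, m1, D1) +
                    0.7 * mvtnorm::dmvnorm(b, m2, D2))
    expect_equal(random_effects_log_density(b, mix), direct, tolerance = 1e-10)
  }
})

test_that("non-positive-definite covariance is rejected", {
  expect_error(re_mixture(1, c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               class = "loda_error_structure")
})

test_that("closed-form marginal density equals the scalar analytic formula", {
  pr <- scalar_params(mu = 1.5, d = 0.5, sigma = 0.7)
  d <- scalar_patient(y = 2.4, t = 0)
  expect_equal(
    marginal_log_density(d, pr, method = "closed_form"),
    dnorm(2.4, 1.5, sqrt(0.5 + 0.49), log = TRUE)
  )
})

test_that("near-degenerate D collapses the marginal onto the conditional at mu", {
  pr <- group_parameters(scalar_specs(), mu = 1.5, D = matrix(1e-12, 1, 1),
                         sigma = c(y = 0.7))
  d <- scalar_patient(y = c(2.4, 1.1))
  expect_equal(marginal_log_density(d, pr, method = "closed_form"),
               conditional_log_density(d, b = 1.5, pr),
               tolerance = 1e-6)
})

test_that("Monte Carlo marginal agrees with the closed form and improves with draws", {
  pr <- toy_gauss_params()
  d <- toy_gauss_patient()
  cf <- marginal_log_density(d, pr, method = "closed_form")
  errs <- vapply(c(1e3, 1e5), function(n) {
    abs(marginal_log_density(d, pr, method = "monte_carlo", n_draws = n,
                             seed = 2024) - cf)
  }, numeric(1))
  expect_lt(errs[2], 0.05)
  expect_lt(errs[2], errs[1])
})

test_that("monte-carlo marginal with a fixed seed is repeatable", {
  pr <- toy_gauss_params()
  d <- toy_gauss_patient()
  m1 <- marginal_log_density(d, pr, method = "monte_carlo", n_draws = 200, seed = 5)
  m2 <- marginal_log_density(d, pr, method = "monte_carlo", n_draws = 200, seed = 5)
  expect_identical(m1, m2)
})

test_that("closed_form marginal refuses non-gaussian markers", {
  prm <- toy_mixed_params()
  expect_error(marginal_log_density(toy_mixed_patient(), prm, method = "closed_form"),
               class = "loda_error_unsupported")
})

test_that("gaussian conditional density peaks at the conditional mean", {
  pr <- scalar_params(mu = 0, d = 1, sigma = 0.5)
  b <- 0.8
  d0 <- scalar_patient(y = b, t = 0) # y equal to conditional mean z'b
  base <- conditional_log_density(d0, b, pr)
  for (eps in c(-0.2, -0.05, 0.05, 0.2)) {
    d_eps <- scalar_patient(y = b + eps, t = 0)
    expect_lt(conditional_log_density(d_eps, b, pr), base)
  }
})

test_that("1-D random-effects density integrates to one", {
  mix <- re_mixture(c(0.4, 0.6), list(-1, 2), list(matrix(0.5), matrix(1.5)))
  f <- function(x) vapply(x, function(xi)
    exp(random_effects_log_density(xi, mix)), numeric(1))
  expect_equal(integrate(f, -15, 15)$value, 1, tolerance = 1e-6)
})

test_that("random-effects estimate matches conjugate-normal algebra", {
  pr <- toy_gauss_params()
  d <- toy_gauss_patient(values_a = c(2.5, 1.6, 1.2), values_b = c(1.6, 1.0, 0.4),
                         times = c(0, 5, 12))
  est <- estimate_random_effects(d, pr, method = "closed_form")
  # independent route: precision-form Bayesian linear model
  mu <- params_mu_test(pr); D <- params_D_test(pr)
  t <- c(0, 5, 12)
  Z <- rbind(cbind(1, t, 0, 0), cbind(0, 0, 1, t))
  y <- c(2.5, 1.6, 1.2, 1.6, 1.0, 0.4)
  Sig <- diag(rep(c(0.3^2, 0.4^2), each = 3))
  P <- solve(D) + t(Z) %*% solve(Sig) %*% Z
  bhat <- solve(P, solve(D) %*% mu + t(Z) %*% solve(Sig) %*% y)
  expect_equal(unname(est), unname(drop(bhat)), tolerance = 1e-9)

  # gaussian Laplace mode coincides with the exact posterior mean
  est_l <- estimate_random_effects(d, pr, method = "laplace")
  expect_equal(est_l, est, tolerance = 1e-6)
})

test_that("a patient with no observations yields the prior mean", {
  pr <- toy_gauss_params()
  empty <- toy_gauss_patient()[0, ]
  expect_equal(unname(estimate_random_effects(empty, pr)),
               params_mu_test(pr))
})

test_that("random-effects estimates shrink toward the mean as noise grows", {
  d <- scalar_patient(y = c(3, 3.2, 2.8))
  ests <- vapply(c(0.2, 0.5, 1, 2, 5), function(s) {
    estimate_random_effects(d, scalar_params(mu = 1.5, d = 0.5, sigma = s))[1]
  }, numeric(1))
  # distance to the prior mean decreases monotonically in sigma
  expect_true(all(diff(abs(ests - 1.5)) < 0))
})

test_that("laplace estimation works on mixed-family data", {
  prm <- toy_mixed_params()
  d <- toy_mixed_patient()
  est <- estimate_random_effects(d, prm, method = "laplace")
  expect_length(est, 5)
  expect_true(all(is.finite(est)))
  # the mode must beat nearby perturbations on the log joint
  obj <- function(b) conditional_log_density(d, b, prm) +
    random_effects_log_density(b, prm)
  f0 <- obj(est)
  set.seed(3)
  for (i in 1:10) expect_lte(obj(est + rnorm(5, 0, 0.05)), f0 + 1e-8)
})
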
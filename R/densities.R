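#' Conditional log density of a patient's observations given random effects
#'
#' The observation model is an exponential-family GLMM per marker with
#' canonical link: for marker r and observation j the linear predictor is
#' `eta = x'alpha_r + z'b` and the response density is normal (with residual
#' SD `sigma_r`), poisson (mean `exp(eta)`) or bernoulli (probability
#' `plogis(eta)`). The conditional density of all observations is the
#' product over markers and observations; this function returns its log.
#'
#' @param data Long-format rows for a single patient.
#' @param b Random-effects vector of length q (the full stacked vector).
#' @param params [group_parameters()] for the group under consideration.
#' @param specs Marker specifications (defaults to those in `params`).
#' @return The log conditional density (a finite scalar for valid inputs).
#' @export
conditional_log_density <- function(data, b, params, specs = params$specs) {
  md <- build_model_data(one_patient(data), specs)
  cond_log_density_md(md, b, params, specs)
}

# Same computation over prebuilt model data (one patient).
cond_log_density_md <- function(md, b, params, specs) {
  if (length(b) != md$q) {
    abort_structure(sprintf("b has length %d but the model has q = %d", length(b), md$q))
  }
  total <- 0
  for (mk in md$markers) {
    if (!length(mk$y)) next
    s <- specs[[mk$name]]
    eta <- drop(mk$Z %*% b[mk$zidx])
    if (ncol(mk$X)) eta <- eta + drop(mk$X %*% params$alpha[[mk$name]])
    if (any(!is.finite(eta))) {
      abort_numeric(sprintf("nonfinite linear predictor for marker '%s', observation %d",
                            mk$name, which(!is.finite(eta))[1L]))
    }
    total <- total + switch(s$family,
      gaussian = sum(dnorm(mk$y, eta, params$sigma[[mk$name]], log = TRUE)),
      poisson = sum(dpois(mk$y, exp(eta), log = TRUE)),
      bernoulli = sum(dbinom(mk$y, 1, plogis(eta), log = TRUE))
    )
  }
  total
}

#' Log density of the random-effects distribution
#'
#' Evaluates the mixture-of-normals random-effects density at `b`; with a
#' single component this is the multivariate normal log density.
#'
#' @param b Random-effects vector of length q.
#' @param mixture An [re_mixture()] (or [group_parameters()], whose mixture
#'   is used).
#' @return The log density.
#' @export
random_effects_log_density <- function(b, mixture) {
  if (inherits(mixture, "group_parameters")) mixture <- mixture$mixture
  if (length(b) != mixture$q) abort_structure("b does not match the mixture dimension")
  comp <- vapply(seq_len(mixture$K), function(k) {
    log(mixture$weights[k]) +
      mvn_log_density(b, mixture$means[[k]], mixture$covariances[[k]])
  }, numeric(1))
  log_sum_exp(comp)
}

# Stack a patient's observations across markers: returns y, mean offset
# X alpha, the full random design Z (n_total x q) and per-row residual
# variances for gaussian rows (used by the closed-form marginal).
stack_gaussian <- function(md, params) {
  y <- numeric(0); off <- numeric(0); vr <- numeric(0)
  Z <- matrix(0, nrow = 0, ncol = md$q)
  for (mk in md$markers) {
    if (!length(mk$y)) next
    n <- length(mk$y)
    Zi <- matrix(0, nrow = n, ncol = md$q)
    Zi[, mk$zidx] <- mk$Z
    o <- if (ncol(mk$X)) drop(mk$X %*% params$alpha[[mk$name]]) else rep(0, n)
    y <- c(y, mk$y); off <- c(off, o); Z <- rbind(Z, Zi)
    vr <- c(vr, rep(params$sigma[[mk$name]]^2, n))
  }
  list(y = y, offset = off, Z = Z, resid_var = vr)
}

all_gaussian <- function(specs) {
  all(vapply(specs, function(s) s$family == "gaussian", logical(1)))
}

#' Marginal log density of a patient's observations
#'
#' The marginal density integrates the conditional observation density over
#' the random-effects distribution. For all-gaussian models with a single
#' mixture component the integral is available in closed form: the stacked
#' observation vector is normal with mean `X alpha + Z mu` and covariance
#' `Z D Z' + diag(residual variances)`. Otherwise a Monte Carlo average of
#' the conditional density over draws from the random-effects distribution
#' is used, stabilised by log-sum-exp.
#'
#' @inheritParams conditional_log_density
#' @param method `"closed_form"` (all-gaussian, K = 1 only) or
#'   `"monte_carlo"`.
#' @param n_draws Number of Monte Carlo draws.
#' @param seed Optional seed making the Monte Carlo evaluation repeatable
#'   (the caller's RNG state is preserved).
#' @return The log marginal density.
#' @export
marginal_log_density <- function(data, params, specs = params$specs,
                                 method = c("closed_form", "monte_carlo"),
                                 n_draws = 500, seed = NULL) {
  method <- match.arg(method)
  specs <- as_marker_specs(specs)
  md <- build_model_data(one_patient(data), specs)
  if (method == "closed_form") {
    if (!all_gaussian(specs) || params$mixture$K != 1L) {
      abort("closed_form marginal density requires all-gaussian markers and K = 1",
            class = "loda_error_unsupported")
    }
    st <- stack_gaussian(md, params)
    V <- st$Z %*% params_D(params) %*% t(st$Z) + diag(st$resid_var, length(st$y))
    return(mvn_log_density(st$y, st$offset + drop(st$Z %*% params_mu(params)), V))
  }
  with_seed(seed, {
    mix <- params$mixture
    comp <- sample.int(mix$K, n_draws, replace = TRUE, prob = mix$weights)
    ll <- vapply(seq_len(n_draws), function(i) {
      bk <- rmvn1(mix$means[[comp[i]]], mix$covariances[[comp[i]]])
      cond_log_density_md(md, bk, params, specs)
    }, numeric(1))
    log_sum_exp(ll) - log(n_draws)
  })
}

#' Estimate a patient's random effects under a group's model
#'
#' Returns the subject-specific random-effects estimate used by the
#' conditional and random-effects prediction approaches. For all-gaussian
#' models the posterior distribution of `b` given the data is normal and
#' the exact posterior mean `mu + D Z' V^-1 (y - X alpha - Z mu)` is
#' returned. For models with poisson or bernoulli markers the posterior
#' mode (Laplace estimate) is located by damped Newton iterations on the
#' log joint density and used as the mean surrogate; in the all-gaussian
#' case the two coincide.
#'
#' A patient with zero observations yields the prior mean `mu`. Estimation
#' is only supported for single-component (K = 1) random-effects
#' distributions.
#'
#' @inheritParams conditional_log_density
#' @param method `"closed_form"` (all-gaussian) or `"laplace"`.
#' @param max_iter,tol Newton iteration controls.
#' @return A named vector of length q.
#' @export
estimate_random_effects <- function(data, params, specs = params$specs,
                                    method = c("closed_form", "laplace"),
                                    max_iter = 50L, tol = 1e-10) {
  method <- match.arg(method)
  specs <- as_marker_specs(specs)
  if (params$mixture$K != 1L) {
    abort("random-effects estimation requires a single mixture component (K = 1)",
          class = "loda_error_unsupported")
  }
  if (nrow(data) == 0L) {
    lay <- re_layout(specs)
    return(setNames(params_mu(params), lay$names))
  }
  md <- build_model_data(one_patient(data), specs)
  mu <- params_mu(params); D <- params_D(params)
  total_obs <- sum(vapply(md$markers, function(m) length(m$y), numeric(1)))
  if (total_obs == 0) return(setNames(mu, md$layout$names))
  if (method == "closed_form") {
    if (!all_gaussian(specs)) {
      abort("closed_form estimation requires all-gaussian markers; use laplace",
            class = "loda_error_unsupported")
    }
    st <- stack_gaussian(md, params)
    V <- st$Z %*% D %*% t(st$Z) + diag(st$resid_var, length(st$y))
    r <- st$y - st$offset - drop(st$Z %*% mu)
    return(setNames(drop(mu + D %*% t(st$Z) %*% solve(V, r)), md$layout$names))
  }
  Dinv <- solve(D)
  b <- mu
  obj <- function(b) conditional_log_density(data, b, params, specs) -
    0.5 * drop(t(b - mu) %*% Dinv %*% (b - mu))
  f <- obj(b)
  for (iter in seq_len(max_iter)) {
    g <- -Dinv %*% (b - mu)
    H <- Dinv
    for (mk in md$markers) {
      if (!length(mk$y)) next
      s <- specs[[mk$name]]
      eta <- drop(mk$Z %*% b[mk$zidx])
      if (ncol(mk$X)) eta <- eta + drop(mk$X %*% params$alpha[[mk$name]])
      gw <- switch(s$family,
        gaussian = list(g = (mk$y - eta) / params$sigma[[mk$name]]^2,
                        w = rep(1 / params$sigma[[mk$name]]^2, length(eta))),
        poisson = list(g = mk$y - exp(eta), w = exp(eta)),
        bernoulli = {
          p <- plogis(eta)
          list(g = mk$y - p, w = p * (1 - p))
        })
      g[mk$zidx] <- g[mk$zidx] + drop(crossprod(mk$Z, gw$g))
      H[mk$zidx, mk$zidx] <- H[mk$zidx, mk$zidx] +
        crossprod(mk$Z, mk$Z * gw$w)
    }
    step <- drop(solve(H, g))
    lambda <- 1
    repeat {
      bn <- b + lambda * step
      fn <- obj(bn)
      if (is.finite(fn) && fn >= f - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    moved <- sqrt(sum((bn - b)^2))
    b <- bn; f <- fn
    if (moved < tol || sqrt(sum(g^2)) < tol) {
      return(setNames(drop(b), md$layout$names))
    }
  }
  if (sqrt(sum(g^2)) > 1e-4) {
    abort_convergence("Newton iterations for the random-effects mode did not converge",
                      last = setNames(drop(b), md$layout$names))
  }
  setNames(drop(b), md$layout$names)
}
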
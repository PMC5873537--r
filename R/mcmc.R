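#' MCMC configuration
#'
#' Settings for the Metropolis-within-Gibbs sampler. The `"paper"` profile
#' mirrors the benchmark study settings (burn-in 500, 1:10 thinning, 10,000
#' retained draws); the `"fast"` profile (burn-in 200, 1:2 thinning, 1,000
#' retained draws) is the desk-scale default used by the shipped simulation
#' study.
#'
#' @param keep Number of retained posterior draws (M).
#' @param burn_in Burn-in iterations (adaptive proposal tuning happens
#'   here).
#' @param thin Thinning interval (>= 1).
#' @param profile Shortcut: `"fast"` or `"paper"`; explicit arguments
#'   override the profile values.
#' @param store_b Keep the per-patient random-effect draws (memory-heavy;
#'   diagnostics only).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(keep = NULL, burn_in = NULL, thin = NULL,
                        profile = c("fast", "paper"), store_b = FALSE) {
  profile <- match.arg(profile)
  def <- switch(profile,
    fast = list(keep = 1000L, burn_in = 200L, thin = 2L),
    paper = list(keep = 10000L, burn_in = 500L, thin = 10L)
  )
  keep <- as.integer(keep %||% def$keep)
  burn_in <- as.integer(burn_in %||% def$burn_in)
  thin <- as.integer(thin %||% def$thin)
  if (keep < 1L) abort_argument("`keep` must be a positive number of retained draws")
  if (burn_in < 0L || thin < 1L) abort_argument("burn_in must be >= 0 and thin >= 1")
  structure(list(keep = keep, burn_in = burn_in, thin = thin,
                 profile = profile, store_b = store_b),
            class = "mcmc_config")
}

# Weakly informative priors. The inverse-Wishart scale for D is
# empirical-Bayes: nu0 = q + 2 with S0 chosen so the prior mean matches the
# spread of per-patient least-squares coefficient estimates (computed in
# `initial_values`), carrying the weight of about two pseudo-patients.
default_priors <- function(q, S0) {
  list(mu_prec = 1e-4, alpha_prec = 1e-4, phi_a = 1, phi_b = 0.005,
       nu0 = q + 2, S0 = S0)
}

# Starting values and the empirical inverse-Wishart scale, from per-marker
# GLM fits (population level) and per-patient least-squares coefficient
# spreads (random-effect level).
initial_values <- function(md) {
  q <- md$q
  mu0 <- numeric(q)
  alpha0 <- list()
  phi0 <- numeric(0)
  s0_diag <- rep(1e-4, q)
  b0 <- matrix(0, nrow = q, ncol = md$n)
  for (mk in md$markers) {
    s <- md$specs[[mk$name]]
    idx <- mk$zidx
    # transform responses to the linear-predictor scale for crude fits
    yl <- switch(s$family,
      gaussian = mk$y,
      poisson = log(pmax(mk$y, 0.5)),
      bernoulli = qlogis(pmin(pmax((mk$y + 0.5) / 2, 0.05), 0.95))
    )
    pooled <- tryCatch(coef(lm(yl ~ mk$t)), error = function(e) c(mean(yl), 0))
    pooled[!is.finite(pooled)] <- 0
    have_int <- s$random_intercept
    have_slope <- s$random_slope
    mu_r <- c(if (have_int) pooled[1], if (have_slope) pooled[2])
    mu0[idx] <- mu_r
    alpha0[[mk$name]] <- if (s$fixed_slope) unname(pooled[2]) else numeric(0)
    # per-patient coefficients for spread and starting b
    co <- matrix(NA_real_, nrow = md$n, ncol = length(idx))
    for (i in seq_len(md$n)) {
      rows <- which(mk$pid == i)
      if (length(rows) >= 2 && have_int && have_slope) {
        fit <- tryCatch(coef(lm(yl[rows] ~ mk$t[rows])), error = function(e) mu_r)
        co[i, ] <- ifelse(is.finite(fit), fit, mu_r)
      } else if (length(rows) >= 1 && have_int && !have_slope) {
        co[i, 1] <- mean(yl[rows])
      } else {
        co[i, ] <- mu_r
      }
    }
    co[!is.finite(co)] <- NA_real_
    for (k in seq_along(idx)) {
      v <- var(co[, k], na.rm = TRUE)
      if (!is.finite(v) || v < 1e-6) v <- 1e-6
      s0_diag[idx[k]] <- v
      b0[idx[k], ] <- ifelse(is.na(co[, k]), mu_r[k], co[, k])
    }
    if (s$family == "gaussian") {
      res <- yl - (b0[idx[1], mk$pid] +
                     if (have_slope) b0[idx[2], mk$pid] * mk$t else 0)
      phi0 <- c(phi0, max(sd(res), 0.05))
    }
  }
  list(mu = mu0, D = diag(s0_diag, q), b = b0, alpha = alpha0,
       phi2 = phi0^2, S0 = diag(s0_diag, q))
}

#' Fit one group's multivariate GLMM by MCMC
#'
#' Bayesian estimation of the group-specific model by Metropolis-within-
#' Gibbs: random effects of gaussian markers, gaussian fixed coefficients,
#' residual variances, the random-effect mean vector and covariance matrix
#' are updated by conjugate draws (normal, inverse-gamma, normal,
#' inverse-Wishart); random effects and fixed coefficients of poisson /
#' bernoulli markers use adaptive random-walk Metropolis steps tuned during
#' burn-in. A single normal random-effects component (K = 1) is fitted.
#'
#' @param data Long-format tibble for the patients of one group (a `group`
#'   column with mixed labels is an error; filter first).
#' @param specs Marker specifications.
#' @param config An [mcmc_config()].
#' @param seed Integer seed; fits are exactly repeatable under it.
#' @param fix_D,fix_phi Hold the random-effects covariance / residual SDs
#'   fixed at their initial values (validation use). Supply the fixed
#'   values via `D0` / `phi0`.
#' @param D0,phi0 Optional fixed values used with `fix_D` / `fix_phi`.
#' @param allow_single Permit a single-patient fit (used by exact
#'   leave-one-out refits of two-patient groups; variance parameters are
#'   then prior-dominated).
#' @return An object of class `loda_fit` carrying the retained draws.
#' @export
fit_group_model <- function(data, specs, config = mcmc_config(), seed = NULL,
                            fix_D = FALSE, fix_phi = FALSE,
                            D0 = NULL, phi0 = NULL, allow_single = FALSE) {
  specs <- as_marker_specs(specs)
  if (!inherits(config, "mcmc_config")) abort_argument("`config` must be an mcmc_config")
  md <- build_model_data(data, specs)
  if (md$n < (if (allow_single) 1L else 2L)) {
    abort_structure("need at least 2 patients to fit a group model")
  }
  grps <- unique(md$groups)
  if (length(grps[!is.na(grps)]) > 1L) {
    abort_structure("data contains more than one group label; fit one group at a time")
  }
  empty <- vapply(md$markers, function(m) length(m$y) == 0L, logical(1))
  if (any(empty)) {
    abort_structure(sprintf("marker '%s' has no observations",
                            md$markers[[which(empty)[1L]]]$name))
  }
  init <- initial_values(md)
  if (!is.null(D0)) init$D <- unname(D0)
  if (!is.null(phi0)) init$phi2 <- unname(phi0)^2
  prior <- default_priors(md$q, init$S0)
  cfg <- list(
    n_burn = config$burn_in, n_thin = config$thin, n_keep = config$keep,
    fix_D = fix_D, fix_phi = fix_phi, store_b = config$store_b,
    prior = prior,
    init = list(mu = init$mu, D = init$D, b = init$b,
                alpha = unname(init$alpha[names(specs)]), phi2 = init$phi2)
  )
  res <- with_seed(seed, cpp_mcmc_mglmm(
    list(n = md$n, q = md$q, markers = md$markers), cfg))
  lay <- md$layout
  colnames(res$mu) <- lay$names
  gauss <- names(specs)[vapply(specs, function(s) s$family == "gaussian", logical(1))]
  colnames(res$phi) <- gauss
  names(res$alpha) <- names(specs)
  names(res$accept_b) <- lay$names[as.integer(names(res$accept_b))]
  names(res$accept_alpha) <- names(specs)
  structure(
    list(
      mu = res$mu, D = res$D, alpha = res$alpha, phi = res$phi,
      b_mean = res$b_mean, b = res$b,
      accept = list(b = unlist(res$accept_b), alpha = unlist(res$accept_alpha)),
      specs = specs, layout = lay, config = config, seed = seed,
      n_patients = md$n, patient_ids = md$ids,
      n_obs = sum(vapply(md$markers, function(m) length(m$y), numeric(1))),
      group = grps[1L]
    ),
    class = "loda_fit"
  )
}

#' @export
print.loda_fit <- function(x, ...) {
  cat(sprintf("<loda_fit> %d patients, %d observations, M = %d retained draws (burn %d, thin %d)\n",
              x$n_patients, x$n_obs, nrow(x$mu), x$config$burn_in, x$config$thin))
  invisible(x)
}

#' Highest posterior density interval from draws
#'
#' The shortest interval containing a `level` fraction of the sorted draws.
#'
#' @param x Numeric vector of posterior draws (length >= 2).
#' @param level Credible level in (0, 1).
#' @return A length-2 vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, level = 0.95) {
  if (!is_scalar_number(level) || level <= 0 || level >= 1) {
    abort_argument("`level` must be a number strictly between 0 and 1")
  }
  xs <- sort(x)
  n <- length(xs)
  k <- max(1L, ceiling(level * n))
  if (k >= n) return(c(xs[1L], xs[n]))
  widths <- xs[(k + 1):n] - xs[1:(n - k)]
  j <- which.min(widths)
  c(xs[j], xs[j + k])
}

# Per-parameter draw matrix on the reporting scale: random-effect means,
# random-effect SDs and correlations, residual SDs, fixed coefficients.
fit_draw_matrix <- function(fit) {
  nm <- fit$layout$names
  q <- length(nm)
  M <- nrow(fit$mu)
  cols <- list()
  for (j in seq_len(q)) cols[[paste0("mu[", nm[j], "]")]] <- fit$mu[, j]
  Dd <- fit$D
  for (j in seq_len(q)) cols[[paste0("sd[", nm[j], "]")]] <- sqrt(Dd[j, j, ])
  if (q > 1) {
    for (j in seq_len(q - 1)) {
      for (k in seq((j + 1), q)) {
        cols[[paste0("corr[", nm[j], ",", nm[k], "]")]] <-
          Dd[j, k, ] / sqrt(Dd[j, j, ] * Dd[k, k, ])
      }
    }
  }
  for (g in colnames(fit$phi)) cols[[paste0("sigma[", g, "]")]] <- fit$phi[, g]
  for (mk in names(fit$alpha)) {
    A <- fit$alpha[[mk]]
    if (is.matrix(A) && ncol(A)) {
      terms <- fixed_terms(fit$specs[[mk]])
      for (p in seq_len(ncol(A))) {
        cols[[paste0("alpha[", mk, ":", terms[p], "]")]] <- A[, p]
      }
    }
  }
  do.call(cbind, cols)
}

#' Posterior summaries of a fitted group model
#'
#' Per parameter: posterior mean, highest posterior density interval at the
#' requested level, and posterior SD. `tidy()` on a `loda_fit` is an alias.
#'
#' @param fit A [fit_group_model()] result.
#' @param level Credible level for the HPD interval.
#' @return A tibble with columns `term`, `estimate`, `sd`, `conf.low`,
#'   `conf.high`.
#' @export
posterior_summary <- function(fit, level = 0.95) {
  if (!inherits(fit, "loda_fit")) abort_argument("`fit` must be a loda_fit")
  if (nrow(fit$mu) < 2L) abort_argument("need at least 2 retained draws")
  draws <- fit_draw_matrix(fit)
  purrr::map_dfr(colnames(draws), function(term) {
    x <- draws[, term]
    h <- hpd_interval(x, level)
    tibble(term = term, estimate = mean(x), sd = sd(x),
           conf.low = h[1L], conf.high = h[2L])
  })
}

#' @rdname posterior_summary
#' @param x A `loda_fit`.
#' @param ... Unused.
#' @export
tidy.loda_fit <- function(x, level = 0.95, ...) posterior_summary(x, level)

#' @export
glance.loda_fit <- function(x, ...) {
  acc <- unlist(x$accept)
  acc <- acc[is.finite(acc)]
  tibble(
    n_patients = x$n_patients, n_obs = x$n_obs, n_draws = nrow(x$mu),
    burn_in = x$config$burn_in, thin = x$config$thin,
    accept_min = if (length(acc)) min(acc, na.rm = TRUE) else NA_real_,
    accept_max = if (length(acc)) max(acc, na.rm = TRUE) else NA_real_
  )
}
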
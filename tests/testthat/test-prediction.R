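# Group-membership probabilities, classification rules and leave-one-out
# prediction.

fit_toy_groups <- function(n0 = 12, n1 = 12, keep = 150, seed = 99) {
  dat <- small_two_group_data(n0, n1, seed = seed)
  cfg <- mcmc_config(keep = keep, burn_in = 100, thin = 1)
  list(
    data = dat,
    fits = list(
      fit_group_model(dplyr::filter(dat, group == 0), toy_gauss_specs(), cfg, seed = 1),
      fit_group_model(dplyr::filter(dat, group == 1), toy_gauss_specs(), cfg, seed = 2)
    )
  )
}

test_that("Bayes normalisation reproduces direct arithmetic", {
  # priors (0.8, 0.2), densities (0.5, 1.0): P_1 = 0.2/(0.8*0.5 + 0.2*1.0)
  p <- bayes_group_probabilities(log(c(0.5, 1.0)), c(0.8, 0.2))
  expect_equal(p[2], 1 / 3)
  expect_equal(sum(p), 1)
  expect_error(bayes_group_probabilities(c(0, 0), c(0.5, 0.4)),
               class = "loda_error_argument")
  expect_error(bayes_group_probabilities(c(-Inf, -Inf), c(0.5, 0.5)),
               class = "loda_error_degenerate")
})

test_that("identical group models give probability one half everywhere", {
  tg <- fit_toy_groups(n0 = 10, n1 = 2, keep = 60)
  fit <- tg$fits[[1]]
  probs <- group_probabilities(small_two_group_data(4, 2, seed = 5),
                               list(fit, fit), priors = c(0.5, 0.5), seed = 3)
  expect_true(all(abs(probs$p_0 - 0.5) < 1e-10))
  expect_true(all(abs(probs$p_0 + probs$p_1 - 1) < 1e-10))
})

test_that("a single group yields probability one", {
  tg <- fit_toy_groups(n0 = 10, n1 = 2, keep = 40)
  probs <- group_probabilities(small_two_group_data(3, 2, seed = 6),
                               tg$fits[1], priors = 1, seed = 3)
  expect_true(all(probs$p_0 == 1))
})

test_that("increasing a group's prior strictly increases its probability", {
  tg <- fit_toy_groups(keep = 80)
  newd <- small_two_group_data(3, 3, seed = 7)
  p_eq <- group_probabilities(newd, tg$fits, priors = c(0.5, 0.5),
                              approaches = "marginal", seed = 3)
  p_sk <- group_probabilities(newd, tg$fits, priors = c(0.8, 0.2),
                              approaches = "marginal", seed = 3)
  expect_true(all(p_sk$p_0 > p_eq$p_0))
})

test_that("the compiled marginal probabilities match per-draw R evaluation", {
  tg <- fit_toy_groups(keep = 25)
  newd <- dplyr::filter(small_two_group_data(2, 2, seed = 8),
                        patient_id == "g0_p001")
  probs <- group_probabilities(newd, tg$fits, priors = c(0.7, 0.3),
                               approaches = "marginal", seed = 3)
  # independent route: closed-form marginal per draw via the R density code
  per_draw <- sapply(seq_len(25), function(m) {
    lf <- vapply(tg$fits, function(f) {
      pr <- group_parameters(toy_gauss_specs(), mu = f$mu[m, ],
                             D = f$D[, , m],
                             sigma = setNames(as.numeric(f$phi[m, ]),
                                              colnames(f$phi)))
      marginal_log_density(newd, pr, method = "closed_form")
    }, numeric(1))
    bayes_group_probabilities(lf, c(0.7, 0.3))
  })
  expect_equal(probs$p_0, mean(per_draw[1, ]), tolerance = 1e-8)
})

test_that("compiled conditional and random-effects densities match the R route", {
  # one synthetic posterior draw per group, mixed families
  prm <- toy_mixed_params()
  q <- 5
  mk_fake_fit <- function(pr, alpha_z) {
    structure(list(
      mu = matrix(params_mu_test(pr), 1, q,
                  dimnames = list(NULL, pr$layout$names)),
      D = array(params_D_test(pr), c(q, q, 1)),
      alpha = list(g = matrix(0, 1, 0), c = matrix(0, 1, 0),
                   z = matrix(alpha_z, 1, 1)),
      phi = matrix(pr$sigma[["g"]], 1, 1, dimnames = list(NULL, "g")),
      specs = pr$specs, layout = pr$layout, n_patients = 2L,
      config = mcmc_config(keep = 1, burn_in = 0, thin = 1)
    ), class = "loda_fit")
  }
  pr2 <- group_parameters(toy_mixed_specs(),
                          mu = params_mu_test(prm) + c(0.5, 0, 0.2, 0, 0.8),
                          D = params_D_test(prm), sigma = c(g = 0.3),
                          alpha = list(z = 0.05))
  fits <- list(mk_fake_fit(prm, 0.02), mk_fake_fit(pr2, 0.05))
  newd <- toy_mixed_patient()
  probs <- group_probabilities(newd, fits, priors = c(0.6, 0.4),
                               approaches = c("conditional", "random_effects"),
                               seed = 3)
  lf_cond <- lf_ran <- numeric(2)
  for (g in 1:2) {
    pr_g <- list(prm, pr2)[[g]]
    bhat <- estimate_random_effects(newd, pr_g, method = "laplace")
    lf_cond[g] <- conditional_log_density(newd, bhat, pr_g)
    lf_ran[g] <- random_effects_log_density(bhat, pr_g)
  }
  expect_equal(probs$p_0[probs$approach == "conditional"],
               bayes_group_probabilities(lf_cond, c(0.6, 0.4))[1],
               tolerance = 1e-6)
  expect_equal(probs$p_0[probs$approach == "random_effects"],
               bayes_group_probabilities(lf_ran, c(0.6, 0.4))[1],
               tolerance = 1e-6)
})

test_that("classification rules follow argmax and strict cutoff semantics", {
  probs <- tibble::tibble(patient_id = c("a", "b", "c"),
                          approach = "marginal",
                          p_0 = c(0.3, 0.5, 0.81), p_1 = c(0.7, 0.5, 0.19))
  cl <- classify_patients(probs, rule = "argmax")
  expect_equal(cl$predicted, c(1L, 0L, 0L)) # tie goes to the lower index
  c1 <- classify_patients(probs[3, ], rule = "cutoff", cutoff = 0.19,
                          positive_group = 1L)
  expect_equal(c1$predicted, 0L)  # 0.19 is not > 0.19
  c2 <- classify_patients(probs[1, ], rule = "cutoff", cutoff = 0.19,
                          positive_group = 1L)
  expect_equal(c2$predicted, 1L)
  c3 <- classify_patients(probs[3, ], rule = "cutoff", cutoff = 0.21,
                          positive_group = 1L)
  expect_equal(c3$predicted, 0L)
  expect_error(classify_patients(probs, rule = "cutoff", cutoff = 1.2),
               class = "loda_error_argument")
})

test_that("draw pairing across groups is enforced", {
  tg <- fit_toy_groups(keep = 30)
  short <- fit_group_model(dplyr::filter(tg$data, group == 1), toy_gauss_specs(),
                           mcmc_config(keep = 20, burn_in = 50, thin = 1), seed = 2)
  expect_error(group_probabilities(small_two_group_data(2, 2, seed = 5),
                                   list(tg$fits[[1]], short)),
               class = "loda_error_structure")
})

test_that("exact leave-one-out performs one refit per held-out patient", {
  dat <- small_two_group_data(2, 2, seed = 31)
  cfg <- mcmc_config(keep = 30, burn_in = 30, thin = 1)
  res <- loocv_predict(dat, toy_gauss_specs(), cfg, approaches = "marginal",
                       mode = "exact", seed = 7)
  expect_equal(attr(res, "n_fits") - 2L, 4L)
  expect_equal(nrow(res), 4L)
  expect_true(all(abs(res$p_0 + res$p_1 - 1) < 1e-10))
})

test_that("fit-once approximates exact leave-one-out closely", {
  # the O(1/n) leave-one-out perturbation is small for the bulk of a
  # 100-patient cohort; individual borderline patients can move more
  dat <- small_two_group_data(50, 50, seed = 41)
  cfg <- mcmc_config(keep = 400, burn_in = 150, thin = 1)
  ex <- loocv_predict(dat, toy_gauss_specs(), cfg, approaches = "marginal",
                      mode = "exact", seed = 7)
  fo <- loocv_predict(dat, toy_gauss_specs(), cfg, approaches = "marginal",
                      mode = "fit_once", seed = 7)
  j <- dplyr::inner_join(ex, fo, by = "patient_id", suffix = c("_ex", "_fo"))
  d <- abs(j$p_0_ex - j$p_0_fo)
  expect_lt(mean(d), 0.05)
  expect_gte(mean(d < 0.05), 0.85)
})

test_that("group sizes below two are rejected for leave-one-out", {
  dat <- small_two_group_data(3, 1, seed = 51)
  expect_error(loocv_predict(dat, toy_gauss_specs(), mcmc_config(keep = 10)),
               class = "loda_error_structure")
})
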
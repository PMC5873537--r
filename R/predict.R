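# Posterior group-membership probabilities.
#
# For a new patient and posterior draw m, Bayes' theorem turns per-group
# predictive densities f_g into membership probabilities
#   P_g = pi_g f_g / sum_g' pi_g' f_g',
# and the reported probability is the average of the per-draw probabilities
# over the M retained draws (average of ratios). The three constructions of
# f_g are: marginal (random effects integrated out), conditional
# (observation density at the subject's estimated random effects under that
# group and draw), random-effects (random-effects density at that
# estimate).

APPROACHES <- c("marginal", "conditional", "random_effects")

#' Bayes group probabilities from log densities
#'
#' The elementary normalisation step: given per-group log predictive
#' densities and prior probabilities, returns the posterior membership
#' probabilities (computed in log space).
#'
#' @param log_f Vector of per-group log densities.
#' @param priors Vector of prior probabilities (nonnegative, summing to 1).
#' @return A probability vector summing to 1.
#' @examples
#' bayes_group_probabilities(log(c(0.5, 1.0)), c(0.8, 0.2))
#' @export
bayes_group_probabilities <- function(log_f, priors) {
  if (length(log_f) != length(priors)) abort_argument("lengths differ")
  if (any(priors < 0) || abs(sum(priors) - 1) > 1e-8) {
    abort_argument("priors must be nonnegative and sum to 1")
  }
  lp <- log_f + log(priors)
  lse <- log_sum_exp(lp)
  if (!is.finite(lse)) {
    abort_degenerate("all predictive densities vanished; probabilities undefined")
  }
  exp(lp - lse)
}

# Extract the draw arrays for the C++ predictor, optionally subsampled.
fit_draws_for_cpp <- function(fit, draw_index = NULL) {
  M <- nrow(fit$mu)
  idx <- draw_index %||% seq_len(M)
  list(
    mu = fit$mu[idx, , drop = FALSE],
    D = fit$D[, , idx, drop = FALSE],
    alpha = lapply(fit$alpha, function(A) A[idx, , drop = FALSE]),
    phi = fit$phi[idx, , drop = FALSE]
  )
}

#' Group-membership probabilities for patients
#'
#' Computes, for every patient in `data`, the posterior probability of
#' belonging to each group under the requested prediction approaches,
#' averaging the per-draw Bayes probabilities over the retained MCMC draws
#' (draws are paired across groups by index, so all fits must carry the
#' same number of draws).
#'
#' For models including poisson or bernoulli markers the marginal density
#' is integrated by importance sampling centred at the Laplace mode of the
#' random effects, with common random numbers shared across groups within
#' each draw; all-gaussian models use the exact closed form.
#'
#' @param data Long-format tibble of the patients to classify (any `group`
#'   column is ignored for the computation).
#' @param fits List of [fit_group_model()] objects, one per group, in group
#'   order.
#' @param priors Prior group probabilities (default: equal).
#' @param approaches Subset of `"marginal"`, `"conditional"`,
#'   `"random_effects"`.
#' @param n_mc Importance-sampling draws per MCMC draw (non-gaussian models
#'   only).
#' @param prediction_draws Optionally use only this many draws, evenly
#'   subsampled from the retained M (paired across groups).
#' @param seed Seed for the integration randomness.
#' @return A tibble with columns `patient_id`, `approach` and `p_0` ...
#'   `p_{G-1}`; each probability row sums to 1.
#' @export
group_probabilities <- function(data, fits, priors = NULL,
                                approaches = APPROACHES,
                                n_mc = 300, prediction_draws = NULL,
                                seed = NULL) {
  approaches <- match.arg(approaches, APPROACHES, several.ok = TRUE)
  if (!length(fits) || !all(vapply(fits, inherits, logical(1), "loda_fit"))) {
    abort_argument("`fits` must be a list of loda_fit objects")
  }
  G <- length(fits)
  Ms <- vapply(fits, function(f) nrow(f$mu), numeric(1))
  if (length(unique(Ms)) != 1L) {
    abort_structure("all group fits must carry the same number of retained draws")
  }
  priors <- priors %||% rep(1 / G, G)
  if (length(priors) != G || any(priors < 0) || abs(sum(priors) - 1) > 1e-8) {
    abort_argument("`priors` must be G nonnegative values summing to 1")
  }
  specs <- fits[[1L]]$specs
  md <- build_model_data(data, specs)
  n_obs_per <- tabulate(unlist(lapply(md$markers, `[[`, "pid")), md$n)
  if (any(n_obs_per == 0)) {
    abort_structure(sprintf("patient '%s' has no observations",
                            md$ids[which(n_obs_per == 0)[1L]]))
  }
  draw_index <- NULL
  if (!is.null(prediction_draws) && prediction_draws < Ms[1L]) {
    draw_index <- unique(round(seq(1L, Ms[1L], length.out = prediction_draws)))
  }
  draws <- lapply(fits, fit_draws_for_cpp, draw_index = draw_index)
  res <- with_seed(seed, cpp_group_probabilities(
    list(n = md$n, q = md$q, markers = md$markers),
    draws, log(priors),
    "marginal" %in% approaches, "conditional" %in% approaches,
    "random_effects" %in% approaches, as.integer(n_mc), 1.2))
  out <- purrr::map_dfr(approaches, function(a) {
    P <- res[[a]]
    colnames(P) <- paste0("p_", seq_len(G) - 1L)
    dplyr::bind_cols(tibble(patient_id = md$ids, approach = a), as_tibble(P))
  })
  out
}

#' Classify patients from group probabilities
#'
#' `argmax` assigns the group with the largest probability (ties go to the
#' lower group index); `cutoff` (two-group only) assigns `positive_group`
#' exactly when its probability strictly exceeds `cutoff`.
#'
#' @param probs Output of [group_probabilities()] or [loocv_predict()].
#' @param rule `"argmax"` or `"cutoff"`.
#' @param cutoff Probability cutoff in `[0, 1]` for the cutoff rule.
#' @param positive_group Group index treated as positive under the cutoff
#'   rule.
#' @return `probs` with a `predicted` integer column appended.
#' @export
classify_patients <- function(probs, rule = c("argmax", "cutoff"),
                              cutoff = 0.5, positive_group = 1L) {
  rule <- match.arg(rule)
  pcols <- grep("^p_[0-9]+$", names(probs), value = TRUE)
  if (!length(pcols)) abort_argument("no probability columns p_0, p_1, ... found")
  P <- as.matrix(probs[pcols])
  if (rule == "argmax") {
    pred <- max.col(P, ties.method = "first") - 1L
  } else {
    if (length(pcols) != 2L) abort_argument("the cutoff rule requires exactly two groups")
    if (!is_scalar_number(cutoff) || cutoff < 0 || cutoff > 1) {
      abort_argument("`cutoff` must be in [0, 1]")
    }
    pos <- paste0("p_", positive_group)
    if (!pos %in% pcols) abort_argument("unknown positive_group")
    other <- setdiff(c(0L, 1L), positive_group)
    pred <- ifelse(probs[[pos]] > cutoff, as.integer(positive_group), other)
  }
  dplyr::mutate(probs, predicted = as.integer(pred))
}

#' Leave-one-out cross-validated group probabilities
#'
#' Fits the group-specific models and predicts every labelled patient.
#' `mode = "exact"` refits the held-out patient's group model without them
#' for each prediction (one refit per patient, on top of the shared
#' fits); `mode = "fit_once"` fits each group once on all its patients and
#' predicts each patient from models that included them -- a documented
#' approximation whose leave-one-out perturbation is O(1/n), used by the
#' desk-scale simulation study.
#'
#' Prior group probabilities default to the training proportions.
#'
#' @param data Long-format tibble with group labels for all patients.
#' @param specs Marker specifications.
#' @param config An [mcmc_config()].
#' @param approaches Prediction approaches to compute.
#' @param mode `"fit_once"` or `"exact"`.
#' @param priors Prior probabilities (default: group proportions).
#' @param n_mc,prediction_draws See [group_probabilities()].
#' @param seed Master seed for fitting and integration.
#' @return A tibble with `patient_id`, `true_group`, `approach`,
#'   `p_0` ... ; attribute `n_fits` records the number of model fits
#'   performed.
#' @export
loocv_predict <- function(data, specs, config = mcmc_config(),
                          approaches = APPROACHES,
                          mode = c("fit_once", "exact"), priors = NULL,
                          n_mc = 300, prediction_draws = NULL, seed = NULL) {
  mode <- match.arg(mode)
  specs <- as_marker_specs(specs)
  data <- validate_long_table(data, specs)
  pat <- dplyr::distinct(data, .data$patient_id, .data$group)
  if (any(is.na(pat$group))) abort_structure("all patients must carry a group label")
  groups <- sort(unique(pat$group))
  sizes <- table(factor(pat$group, levels = groups))
  if (any(sizes < 2)) {
    abort_structure("every group needs at least 2 patients for leave-one-out fitting")
  }
  G <- length(groups)
  priors <- priors %||% as.numeric(sizes / sum(sizes))
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max, 1L), G + nrow(pat) + 1L)
  fits <- purrr::map(seq_along(groups), function(g) {
    fit_group_model(dplyr::filter(data, .data$group == groups[g]), specs,
                    config, seed = seeds[g])
  })
  n_fits <- G
  if (mode == "fit_once") {
    res <- group_probabilities(data, fits, priors, approaches,
                               n_mc = n_mc, prediction_draws = prediction_draws,
                               seed = seeds[G + 1L])
  } else {
    res <- purrr::map_dfr(seq_len(nrow(pat)), function(i) {
      id <- pat$patient_id[i]
      g <- match(pat$group[i], groups)
      train <- dplyr::filter(data, .data$group == groups[g],
                             .data$patient_id != id)
      refit <- fit_group_model(train, specs, config, seed = seeds[g],
                               allow_single = TRUE)
      n_fits <<- n_fits + 1L
      fit_set <- fits
      fit_set[[g]] <- refit
      group_probabilities(dplyr::filter(data, .data$patient_id == id),
                          fit_set, priors, approaches, n_mc = n_mc,
                          prediction_draws = prediction_draws,
                          seed = seeds[G + 1L + i])
    })
  }
  out <- dplyr::left_join(res, dplyr::rename(pat, true_group = "group"),
                          by = "patient_id")
  out <- dplyr::relocate(out, "patient_id", "true_group", "approach")
  attr(out, "n_fits") <- n_fits
  attr(out, "fits") <- fits
  out
}
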
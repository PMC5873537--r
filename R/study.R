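# Simulation-study orchestration: replicate generation, per-group fitting,
# cross-validated prediction under the three approaches, per-replicate
# ROC-optimal metrics and parameter-recovery aggregation.

#' Simulation study configuration
#'
#' Defaults are the desk-scale profile: 10 replicates, the fast MCMC
#' profile, fit-once cross-validation and 300 integration draws. The
#' benchmark-scale settings (100 replicates, burn-in 500, 1:10 thinning,
#' M = 10,000, exact leave-one-out) are available via
#' `mcmc = mcmc_config(profile = "paper")`, `n_replicates = 100`,
#' `mode = "exact"`.
#'
#' @param n_replicates Number of simulated datasets (>= 1).
#' @param mcmc An [mcmc_config()].
#' @param mode Cross-validation mode, see [loocv_predict()].
#' @param approaches Prediction approaches to evaluate.
#' @param n_mc Integration draws per retained MCMC draw.
#' @param prediction_draws MCMC draws used for prediction (subsampled
#'   evenly from the retained M; `NULL` = all).
#' @param positive_group Group treated as positive (poor prognosis).
#' @param priors Prior group probabilities (`NULL` = training proportions).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param fit_only Skip prediction and evaluation, returning recovery
#'   summaries only.
#' @param groups Optional subset of group indices to fit when `fit_only`.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_replicates = 10L, mcmc = mcmc_config(profile = "fast"),
                         mode = c("fit_once", "exact"),
                         approaches = APPROACHES, n_mc = 300L,
                         prediction_draws = NULL, positive_group = 1L,
                         priors = NULL, seed = 1L, fit_only = FALSE,
                         groups = NULL) {
  mode <- match.arg(mode)
  if (n_replicates < 1L) abort_argument("need at least one replicate")
  structure(
    list(n_replicates = as.integer(n_replicates), mcmc = mcmc, mode = mode,
         approaches = approaches, n_mc = as.integer(n_mc),
         prediction_draws = prediction_draws,
         positive_group = as.integer(positive_group), priors = priors,
         seed = as.integer(seed), fit_only = fit_only, groups = groups),
    class = "study_config"
  )
}

run_one_replicate <- function(scenario, cfg, rep_seed) {
  seeds <- derive_seeds(rep_seed, 10L)
  sim <- simulate_dataset(scenario, seed = seeds[1L])
  groups <- sort(unique(sim$group))
  fit_groups <- cfg$groups %||% groups
  recovery <- list()
  if (cfg$fit_only) {
    for (g in fit_groups) {
      fit <- fit_group_model(dplyr::filter(sim, .data$group == g),
                             scenario$specs, cfg$mcmc, seed = seeds[4L + g])
      recovery[[as.character(g)]] <-
        dplyr::mutate(posterior_summary(fit), group = g, .before = 1)
    }
    return(list(recovery = dplyr::bind_rows(recovery), metrics = NULL))
  }
  pred <- loocv_predict(sim, scenario$specs, cfg$mcmc,
                        approaches = cfg$approaches, mode = cfg$mode,
                        priors = cfg$priors, n_mc = cfg$n_mc,
                        prediction_draws = cfg$prediction_draws,
                        seed = seeds[3L])
  for (g in groups) {
    fit <- attr(pred, "fits")[[match(g, groups)]]
    recovery[[as.character(g)]] <-
      dplyr::mutate(posterior_summary(fit), group = g, .before = 1)
  }
  pos <- paste0("p_", cfg$positive_group)
  metrics <- purrr::map_dfr(unique(pred$approach), function(a) {
    sub <- dplyr::filter(pred, .data$approach == a)
    scores <- sub[[pos]]
    labels <- as.integer(sub$true_group == cfg$positive_group)
    roc <- roc_curve(scores, labels)
    copt <- optimal_cutoff(roc)
    dplyr::mutate(metrics_at_cutoff(scores, labels, copt),
                  approach = a, .before = 1)
  })
  list(recovery = dplyr::bind_rows(recovery), metrics = metrics)
}

#' Run the simulation study
#'
#' For each replicate: simulate a dataset from the scenario, fit the
#' group-specific models by MCMC, compute cross-validated group
#' probabilities under the requested approaches, select the per-replicate
#' ROC-optimal cutoff and record accuracy metrics; finally aggregate mean
#' accuracy per approach and parameter recovery per group. Replicates that
#' fail are logged and excluded from the averages; more than 20% failures
#' aborts the study.
#'
#' @param scenario A [builtin_scenario()] / [scenario_definition()], or its
#'   name.
#' @param config A [study_config()].
#' @return An object of class `loda_study` with elements `accuracy` (mean
#'   metrics per approach), `per_replicate` (metric rows per replicate),
#'   `recovery` (per group, against the scenario truths), `failures` and
#'   `config`.
#' @export
run_study <- function(scenario, config = study_config()) {
  if (is.character(scenario)) scenario <- builtin_scenario(scenario)
  if (!inherits(config, "study_config")) abort_argument("`config` must be a study_config")
  rep_seeds <- derive_seeds(config$seed, config$n_replicates)
  results <- vector("list", config$n_replicates)
  failures <- character(0)
  for (r in seq_len(config$n_replicates)) {
    results[[r]] <- tryCatch(
      run_one_replicate(scenario, config, rep_seeds[r]),
      error = function(e) {
        failures <<- c(failures,
                       sprintf("replicate %d: %s", r, conditionMessage(e)))
        NULL
      }
    )
  }
  ok <- !vapply(results, is.null, logical(1))
  if (mean(!ok) > 0.2) {
    abort(paste0("more than 20% of replicates failed:\n",
                 paste(failures, collapse = "\n")), class = "loda_error_study")
  }
  results <- results[ok]
  reps <- which(ok)
  per_replicate <- purrr::map_dfr(seq_along(results), function(k) {
    m <- results[[k]]$metrics
    if (is.null(m)) return(NULL)
    dplyr::mutate(m, replicate = reps[k], .before = 1)
  })
  accuracy <- NULL
  if (nrow(per_replicate %||% tibble())) {
    accuracy <- per_replicate |>
      dplyr::group_by(.data$approach) |>
      dplyr::summarise(dplyr::across(c("cutoff", "sensitivity", "specificity",
                                       "pcc", "auc", "ppv", "npv"),
                                     ~ mean(.x, na.rm = TRUE)),
                       .groups = "drop")
  }
  truths <- scenario_truths(scenario)
  recovery_all <- purrr::map_dfr(seq_along(results), function(k) {
    dplyr::mutate(results[[k]]$recovery, replicate = reps[k], .before = 1)
  })
  recovery <- purrr::map(
    setNames(sort(unique(recovery_all$group)),
             paste0("group_", sort(unique(recovery_all$group)))),
    function(g) {
      recovery_summary(dplyr::filter(recovery_all, .data$group == g),
                       dplyr::filter(truths, .data$group == g)[c("term", "truth")])
    })
  structure(
    list(scenario = scenario$name, accuracy = accuracy,
         per_replicate = per_replicate, recovery = recovery,
         replicate_summaries = recovery_all,
         failures = failures, config = config),
    class = "loda_study"
  )
}

#' @export
print.loda_study <- function(x, ...) {
  cat(sprintf("<loda_study> %s: %d replicate(s), %d failure(s)\n",
              x$scenario,
              length(unique(x$replicate_summaries$replicate)), length(x$failures)))
  if (!is.null(x$accuracy)) {
    cat("mean accuracy at per-replicate optimal cutoffs:\n")
    print(as.data.frame(x$accuracy), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write study result tables to a directory
#'
#' Emits delimited tables: `accuracy.csv` (metric rows, one column per
#' approach), `per_replicate.csv`, one `recovery_group<g>.csv` per group,
#' and a `manifest.yaml` recording the package version, master seed and a
#' configuration hash.
#'
#' @param study A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_tables <- function(study, dir) {
  if (!inherits(study, "loda_study")) abort_argument("`study` must be a loda_study")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  approaches <- c("random_effects", "marginal", "conditional")
  acc <- study$accuracy
  metric_names <- c("cutoff", "sensitivity", "specificity", "pcc", "auc",
                    "ppv", "npv")
  wide <- tibble(metric = metric_names)
  if (!is.null(acc)) {
    for (a in intersect(approaches, acc$approach)) {
      row <- acc[acc$approach == a, ]
      wide[[a]] <- as.numeric(row[1, metric_names])
    }
  }
  readr::write_csv(wide, file.path(dir, "accuracy.csv"))
  if (!is.null(study$per_replicate) && nrow(study$per_replicate %||% tibble())) {
    readr::write_csv(study$per_replicate, file.path(dir, "per_replicate.csv"))
  }
  for (nm in names(study$recovery)) {
    readr::write_csv(study$recovery[[nm]],
                     file.path(dir, paste0("recovery_", nm, ".csv")))
  }
  cfg <- study$config
  manifest <- list(
    package = "loda",
    version = as.character(utils::packageVersion("loda")),
    scenario = study$scenario,
    seed = cfg$seed,
    n_replicates = cfg$n_replicates,
    config_hash = rlang::hash(cfg),
    failures = length(study$failures)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Plot per-replicate accuracy dispersion
#'
#' Histogram-style comparison of the per-replicate sensitivity,
#' specificity, PCC and AUC across prediction approaches, mirroring the
#' per-dataset variability display of the simulation study.
#'
#' @param object A [run_study()] result (with prediction enabled).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.loda_study <- function(object, ...) {
  pr <- object$per_replicate
  if (is.null(pr) || !nrow(pr)) abort_argument("study carries no per-replicate metrics")
  long <- tidyr::pivot_longer(pr, c("sensitivity", "specificity", "pcc", "auc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$approach)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5, bins = 20) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "replicates")
}
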
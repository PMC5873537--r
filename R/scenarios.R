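# Built-in simulation scenarios.
#
# Two benchmark scenarios emulate a primary biliary cirrhosis surveillance
# cohort: 200 good-prognosis (group 0) and 50 poor-prognosis (group 1)
# patients, four clinic visits (day 0 plus uniform draws in the windows
# (170,200), (350,390), (710,770) days, converted to months), and shared
# correlated random intercepts/slopes across markers.
#
# Scenario 1: four markers (albumin and log-bilirubin gaussian, platelet
# count poisson, blood-vessel-malformation indicator bernoulli with a fixed
# time slope); the groups differ in the random-effect means / fixed slopes
# while sharing the covariance D -- a mean-profile contrast.
#
# Scenario 2: only the two gaussian markers; means and D identical across
# groups and small relative to the residual error; the groups differ only
# in the residual SDs -- a measurement-error contrast.

scenario1_spec_list <- function() {
  marker_specs(
    marker_spec("albumin", "gaussian"),
    marker_spec("lbili", "gaussian"),
    marker_spec("platelet", "poisson"),
    marker_spec("bvm", "bernoulli", random_slope = FALSE, fixed_slope = TRUE)
  )
}

scenario2_spec_list <- function() {
  marker_specs(
    marker_spec("albumin", "gaussian"),
    marker_spec("lbili", "gaussian")
  )
}

# Correlations shared by both groups (scenario 1; scenario 2 uses the
# subset among the gaussian effects).
scenario_correlations <- function() {
  tibble(
    a = c("albumin:int", "albumin:int", "albumin:int", "albumin:int",
          "albumin:int", "albumin:int",
          "albumin:slope", "albumin:slope", "albumin:slope", "albumin:slope",
          "albumin:slope",
          "lbili:int", "lbili:int", "lbili:int", "lbili:int",
          "lbili:slope", "lbili:slope", "lbili:slope",
          "platelet:int", "platelet:int",
          "platelet:slope"),
    b = c("albumin:slope", "lbili:int", "lbili:slope", "platelet:int",
          "platelet:slope", "bvm:int",
          "lbili:int", "lbili:slope", "platelet:int", "platelet:slope",
          "bvm:int",
          "lbili:slope", "platelet:int", "platelet:slope", "bvm:int",
          "platelet:int", "platelet:slope", "bvm:int",
          "platelet:slope", "bvm:int",
          "bvm:int"),
    corr = c(-6.46e-2, -1.97e-1, 2.11e-1, 1.91e-1,
             1.09e-1, -3.48e-1,
             1.57e-3, -2.33e-1, -2.57e-1, -2.60e-1,
             2.27e-1,
             -1.75e-1, 2.47e-1, -1.87e-1, 2.70e-1,
             -1.69e-1, 1.25e-1, 8.13e-3,
             6.14e-2, -2.48e-1,
             -8.03e-2)
  )
}

scenario1_parameters <- function() {
  specs <- scenario1_spec_list()
  sds <- c("albumin:int" = 2.64e-1, "albumin:slope" = 7.76e-3,
           "lbili:int" = 8.45e-1, "lbili:slope" = 1.49e-2,
           "platelet:int" = 3.45e-1, "platelet:slope" = 1.51e-2,
           "bvm:int" = 1.88)
  D <- assemble_covariance(sds, scenario_correlations())
  list(
    group_parameters(
      specs,
      mu = c(3.69, -6.83e-3, 2.13e-2, 9.94e-3, 5.54, -4.29e-3, -2.54),
      D = D,
      sigma = c(albumin = 3.18e-1, lbili = 3.38e-1),
      alpha = list(bvm = 1.46e-2)
    ),
    group_parameters(
      specs,
      mu = c(3.39, -1.44e-2, 1.23, 2.38e-2, 5.46, -1.14e-2, -6.81e-1),
      D = D,
      sigma = c(albumin = 3.14e-1, lbili = 3.96e-1),
      alpha = list(bvm = 4.81e-2)
    )
  )
}

scenario2_parameters <- function() {
  specs <- scenario2_spec_list()
  sds <- c("albumin:int" = 6.50e-2, "albumin:slope" = 7.76e-3,
           "lbili:int" = 1.12e-2, "lbili:slope" = 1.49e-2)
  corr <- dplyr::filter(scenario_correlations(),
                        .data$a %in% names(sds), .data$b %in% names(sds))
  D <- assemble_covariance(sds, corr)
  mu <- c(3.00, 0, 1.00, 0)
  list(
    group_parameters(specs, mu = mu, D = D,
                     sigma = c(albumin = 3.14e-1, lbili = 3.95e-1)),
    group_parameters(specs, mu = mu, D = D,
                     sigma = c(albumin = 1.59e-1, lbili = 1.69e-1))
  )
}

#' Scenario definitions for the simulation study
#'
#' `builtin_scenario()` returns one of the two shipped benchmark scenarios;
#' `scenario_definition()` builds a custom one.
#'
#' @param name `"scenario1"` or `"scenario2"`.
#' @return An object of class `loda_scenario` with fields `name`,
#'   `group_sizes`, `visit_windows` (day pairs for visits after the day-0
#'   visit), `day_to_month` (conversion factor applied to simulated visit
#'   days), `specs` and `params` (a list of [group_parameters()], one per
#'   group).
#' @export
builtin_scenario <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("scenario1", "scenario2")) {
    abort_argument("unknown scenario; available: scenario1, scenario2")
  }
  params <- switch(name, scenario1 = scenario1_parameters(),
                   scenario2 = scenario2_parameters())
  scenario_definition(
    name = name,
    group_sizes = c(200L, 50L),
    visit_windows = list(c(170, 200), c(350, 390), c(710, 770)),
    specs = params[[1L]]$specs,
    params = params
  )
}

#' @param group_sizes Integer vector of patients per group.
#' @param visit_windows List of `c(lo, hi)` day windows, one per visit after
#'   the day-0 visit; must be increasing and non-overlapping.
#' @param specs Marker specifications shared by all groups.
#' @param params List of [group_parameters()], one per group.
#' @param day_to_month Conversion factor from simulated visit days to model
#'   months.
#' @rdname builtin_scenario
#' @export
scenario_definition <- function(name, group_sizes, visit_windows, specs, params,
                                day_to_month = DAYS_PER_MONTH_FACTOR) {
  if (any(group_sizes < 1)) abort_argument("group sizes must be positive")
  if (length(params) != length(group_sizes)) {
    abort_structure("need one group_parameters per group")
  }
  prev_hi <- -Inf
  for (w in visit_windows) {
    if (length(w) != 2 || w[1] >= w[2]) abort_structure("each visit window must be c(lo, hi) with lo < hi")
    if (w[1] < prev_hi) abort_structure("visit windows must be increasing and non-overlapping")
    prev_hi <- w[2]
  }
  structure(
    list(name = name, group_sizes = as.integer(group_sizes),
         visit_windows = visit_windows, day_to_month = day_to_month,
         specs = as_marker_specs(specs), params = params),
    class = "loda_scenario"
  )
}

#' @export
print.loda_scenario <- function(x, ...) {
  cat(sprintf("<loda_scenario> %s: groups of %s patients, %d visits, %d markers\n",
              x$name, paste(x$group_sizes, collapse = "/"),
              length(x$visit_windows) + 1L, length(x$specs)))
  invisible(x)
}

#' True parameter values of a scenario, in tidy form
#'
#' One row per (group, parameter) with terms named as in [tidy.loda_fit()]:
#' `mu[effect]`, `sd[effect]`, `corr[effect1,effect2]`, `sigma[marker]`,
#' `alpha[marker:time]`. Used as the truth table for
#' [recovery_summary()].
#'
#' @param scenario A `loda_scenario`.
#' @return A tibble with columns `group`, `term`, `truth`.
#' @export
scenario_truths <- function(scenario) {
  purrr::map_dfr(seq_along(scenario$params), function(g) {
    p <- scenario$params[[g]]
    nm <- p$layout$names
    mu <- params_mu(p); D <- params_D(p)
    sds <- sqrt(diag(D))
    rows <- list(
      tibble(term = paste0("mu[", nm, "]"), truth = mu),
      tibble(term = paste0("sd[", nm, "]"), truth = sds)
    )
    if (length(nm) > 1) {
      idx <- which(upper.tri(D), arr.ind = TRUE)
      rows <- c(rows, list(tibble(
        term = paste0("corr[", nm[idx[, 1]], ",", nm[idx[, 2]], "]"),
        truth = D[idx] / (sds[idx[, 1]] * sds[idx[, 2]])
      )))
    }
    if (length(p$sigma)) {
      rows <- c(rows, list(tibble(term = paste0("sigma[", names(p$sigma), "]"),
                                  truth = unname(p$sigma))))
    }
    for (mk in names(p$alpha)) {
      if (length(p$alpha[[mk]])) {
        rows <- c(rows, list(tibble(
          term = paste0("alpha[", mk, ":", fixed_terms(p$specs[[mk]]), "]"),
          truth = unname(p$alpha[[mk]]))))
      }
    }
    dplyr::bind_rows(rows) |> dplyr::mutate(group = g - 1L, .before = 1)
  })
}
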
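# Scenario configuration files (YAML), mirroring the generative-parameter
# table row structure: per-group random-effect means and SDs keyed by
# effect, pairwise correlations, residual SDs and fixed coefficients.

SCENARIO_KEYS <- c("name", "group_sizes", "visit_windows", "day_to_month",
                   "markers", "groups")
MARKER_KEYS <- c("name", "family", "random_intercept", "random_slope",
                 "fixed_slope")
GROUP_KEYS <- c("mean", "sd", "corr", "residual_sd", "fixed")

#' Read / write scenario configuration files
#'
#' Scenario definitions are stored as YAML with explicit per-effect keys
#' (e.g. `"albumin:int"`), one `groups` entry per prognostic group.
#' Unknown keys and out-of-range values are rejected.
#'
#' @param path File path.
#' @return `load_scenario_config()` returns a [scenario_definition()];
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
load_scenario_config <- function(path) {
  if (!file.exists(path)) abort_argument(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), SCENARIO_KEYS)
  if (length(unknown)) {
    abort_config(paste0("unknown configuration keys: ",
                        paste(unknown, collapse = ", ")))
  }
  need <- setdiff(SCENARIO_KEYS[SCENARIO_KEYS != "day_to_month"], names(raw))
  if (length(need)) {
    abort_config(paste0("missing configuration keys: ", paste(need, collapse = ", ")))
  }
  specs <- marker_specs(lapply(raw$markers, function(m) {
    unknown <- setdiff(names(m), MARKER_KEYS)
    if (length(unknown)) {
      abort_config(paste0("unknown marker keys: ", paste(unknown, collapse = ", ")))
    }
    marker_spec(m$name, m$family,
                random_intercept = isTRUE(m$random_intercept),
                random_slope = isTRUE(m$random_slope),
                fixed_slope = isTRUE(m$fixed_slope))
  }))
  lay <- re_layout(specs)
  params <- lapply(raw$groups, function(g) {
    unknown <- setdiff(names(g), GROUP_KEYS)
    if (length(unknown)) {
      abort_config(paste0("unknown group keys: ", paste(unknown, collapse = ", ")))
    }
    mu <- unlist(g$mean)
    sds <- unlist(g$sd)
    if (!setequal(names(mu), lay$names) || !setequal(names(sds), lay$names)) {
      abort_config("group mean/sd entries must cover exactly the random effects")
    }
    corr <- NULL
    if (length(g$corr)) {
      corr <- purrr::map_dfr(g$corr, function(x) {
        if (length(x) != 3L) abort_config("each corr entry must be [effect, effect, value]")
        val <- suppressWarnings(as.numeric(x[[3L]]))
        if (is.na(val)) abort_config("correlation value is not numeric")
        tibble(a = as.character(x[[1L]]), b = as.character(x[[2L]]), corr = val)
      })
    }
    D <- assemble_covariance(sds[lay$names], corr)
    sigma <- unlist(g$residual_sd) %||% numeric(0)
    alpha <- lapply(g$fixed %||% list(), function(a) as.numeric(unlist(a)))
    group_parameters(specs, mu = unname(mu[lay$names]), D = D,
                     sigma = sigma, alpha = alpha)
  })
  scenario_definition(
    name = raw$name,
    group_sizes = as.integer(unlist(raw$group_sizes)),
    visit_windows = lapply(raw$visit_windows, as.numeric),
    specs = specs,
    params = params,
    day_to_month = raw$day_to_month %||% DAYS_PER_MONTH_FACTOR
  )
}

#' @param scenario A [scenario_definition()] to serialise.
#' @rdname load_scenario_config
#' @export
write_scenario_config <- function(scenario, path) {
  if (!inherits(scenario, "loda_scenario")) abort_argument("`scenario` must be a loda_scenario")
  lay <- re_layout(scenario$specs)
  out <- list(
    name = scenario$name,
    group_sizes = as.integer(scenario$group_sizes),
    visit_windows = lapply(scenario$visit_windows, as.numeric),
    day_to_month = scenario$day_to_month,
    markers = lapply(unclass(scenario$specs), function(s) {
      list(name = s$name, family = s$family,
           random_intercept = s$random_intercept,
           random_slope = s$random_slope, fixed_slope = s$fixed_slope)
    }),
    groups = lapply(scenario$params, function(p) {
      mu <- params_mu(p); D <- params_D(p)
      sds <- sqrt(diag(D))
      corr <- list()
      if (length(mu) > 1) {
        idx <- which(upper.tri(D) & abs(D) > 0, arr.ind = TRUE)
        corr <- lapply(seq_len(nrow(idx)), function(k) {
          i <- idx[k, 1]; j <- idx[k, 2]
          list(lay$names[i], lay$names[j],
               D[i, j] / (sds[i] * sds[j]))
        })
      }
      g <- list(mean = as.list(setNames(mu, lay$names)),
                sd = as.list(setNames(sds, lay$names)),
                corr = corr)
      if (length(p$sigma)) g$residual_sd <- as.list(p$sigma)
      al <- p$alpha[vapply(p$alpha, length, integer(1)) > 0]
      if (length(al)) g$fixed <- lapply(al, as.list)
      g
    })
  )
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}
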
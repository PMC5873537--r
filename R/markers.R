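#' Declare a longitudinal marker
#'
#' A marker specification records the response family of one longitudinal
#' marker together with its design: which of a random intercept, a random
#' time slope and a fixed time slope enter the linear predictor. The link is
#' canonical and fixed by the family (identity for gaussian, log for
#' poisson, logit for bernoulli); gaussian markers additionally carry a
#' residual standard deviation (dispersion).
#'
#' A marker must have at least one random term, and may not have both a
#' random slope and a separate fixed slope (they would be confounded).
#'
#' @param name Marker label, used to match rows of long-format data.
#' @param family One of `"gaussian"`, `"poisson"`, `"bernoulli"`.
#' @param random_intercept,random_slope Include a random intercept / random
#'   time slope for this marker?
#' @param fixed_slope Include a fixed (population) time slope? Only allowed
#'   when `random_slope` is `FALSE`.
#'
#' @return An object of class `marker_spec`.
#' @examples
#' marker_spec("albumin", "gaussian", random_slope = TRUE)
#' marker_spec("bvm", "bernoulli", random_slope = FALSE, fixed_slope = TRUE)
#' @export
marker_spec <- function(name,
                        family = c("gaussian", "poisson", "bernoulli"),
                        random_intercept = TRUE,
                        random_slope = TRUE,
                        fixed_slope = FALSE) {
  family <- match.arg(family)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_argument("`name` must be a non-empty string")
  }
  if (!random_intercept && !random_slope) {
    abort_structure("a marker needs at least one random term (intercept or slope)")
  }
  if (random_slope && fixed_slope) {
    abort_structure("a marker cannot have both a random and a fixed time slope")
  }
  structure(
    list(
      name = name,
      family = family,
      link = switch(family, gaussian = "identity", poisson = "log",
                    bernoulli = "logit"),
      random_intercept = random_intercept,
      random_slope = random_slope,
      fixed_slope = fixed_slope,
      dispersion = family == "gaussian"
    ),
    class = "marker_spec"
  )
}

#' @export
print.marker_spec <- function(x, ...) {
  terms <- c(
    if (x$random_intercept) "random intercept",
    if (x$random_slope) "random slope",
    if (x$fixed_slope) "fixed slope"
  )
  cat(sprintf("<marker_spec> %s: %s(%s); %s\n", x$name, x$family, x$link,
              paste(terms, collapse = " + ")))
  invisible(x)
}

#' Bundle marker specifications
#'
#' @param ... `marker_spec` objects (or a single list of them).
#' @return A named list of class `marker_specs`.
#' @examples
#' marker_specs(marker_spec("alb", "gaussian"), marker_spec("plt", "poisson"))
#' @export
marker_specs <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1L]], "marker_spec")) {
    specs <- specs[[1L]]
  }
  ok <- vapply(specs, inherits, logical(1), "marker_spec")
  if (length(specs) == 0L || !all(ok)) {
    abort_argument("all elements must be marker_spec objects")
  }
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) abort_structure("duplicate marker names")
  structure(setNames(specs, nm), class = "marker_specs")
}

as_marker_specs <- function(specs) {
  if (inherits(specs, "marker_specs")) return(specs)
  marker_specs(specs)
}

# Random-effect layout: names and 1-based indices of each marker's random
# terms within the stacked random-effects vector b.
re_layout <- function(specs) {
  specs <- as_marker_specs(specs)
  idx <- list()
  names_q <- character(0)
  at <- 0L
  for (s in specs) {
    terms <- c(if (s$random_intercept) "int", if (s$random_slope) "slope")
    idx[[s$name]] <- at + seq_along(terms)
    names_q <- c(names_q, paste0(s$name, ":", terms))
    at <- at + length(terms)
  }
  list(index = idx, names = names_q, q = at)
}

re_names <- function(specs) re_layout(specs)$names

# Fixed-design column labels for one marker (time-only designs).
fixed_terms <- function(spec) if (spec$fixed_slope) "time" else character(0)

# Design matrices for one marker at observation times t (months).
marker_design <- function(spec, t) {
  Z <- cbind(
    if (spec$random_intercept) rep(1, length(t)),
    if (spec$random_slope) t
  )
  X <- if (spec$fixed_slope) matrix(t, ncol = 1) else
    matrix(0, nrow = length(t), ncol = 0)
  list(X = X, Z = Z)
}

value_domain_ok <- function(family, value) {
  switch(family,
    gaussian = is.finite(value),
    poisson = is.finite(value) & value >= 0 & value == round(value),
    bernoulli = value %in% c(0, 1)
  )
}
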
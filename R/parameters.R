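#' Mixture-of-normals random-effects distribution
#'
#' The joint distribution of a group's stacked random-effects vector is a
#' K-component mixture of multivariate normals. Model fitting in this
#' package uses a single component (K = 1); the density machinery supports
#' general K.
#'
#' @param weights Component weights (nonnegative, summing to 1).
#' @param means List of component mean vectors (or a single vector for K = 1).
#' @param covariances List of component covariance matrices (or one matrix).
#' @return An object of class `re_mixture`.
#' @examples
#' re_mixture(1, c(0, 0), diag(2))
#' @export
re_mixture <- function(weights, means, covariances) {
  if (is.numeric(means)) means <- list(means)
  if (is.matrix(covariances)) covariances <- list(covariances)
  K <- length(weights)
  if (length(means) != K || length(covariances) != K) {
    abort_structure("weights, means and covariances must have equal length K")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    abort_structure("mixture weights must be nonnegative and sum to 1")
  }
  q <- length(means[[1L]])
  for (k in seq_len(K)) {
    if (length(means[[k]]) != q) abort_structure("mixture components disagree on dimension q")
    Dk <- covariances[[k]]
    if (!is.matrix(Dk) || any(dim(Dk) != q)) {
      abort_structure("each covariance must be a q x q matrix")
    }
    if (max(abs(Dk - t(Dk))) > 1e-8) abort_structure("covariance matrix is not symmetric")
    ev <- eigen(Dk, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) abort_structure("covariance matrix is not positive definite")
  }
  structure(list(weights = as.numeric(weights), means = lapply(means, as.numeric),
                 covariances = covariances, K = K, q = q),
            class = "re_mixture")
}

#' Group-specific model parameters
#'
#' Collects everything that defines one prognostic group's multivariate
#' generalised linear mixed model: the random-effects distribution (whose
#' means play the role of population intercepts/slopes for markers with the
#' corresponding random terms), fixed coefficients for markers that have
#' them, and residual standard deviations for gaussian markers.
#'
#' @param specs Marker specifications (see [marker_specs()]).
#' @param mu Random-effects mean vector (length q, ordered per marker:
#'   intercept then slope), used when `mixture` is not given (K = 1).
#' @param D Random-effects covariance matrix (q x q), used with `mu`.
#' @param sigma Named vector of residual SDs, one per gaussian marker.
#' @param alpha Named list of fixed-coefficient vectors (only markers with
#'   fixed terms; time slope only in the shipped designs).
#' @param mixture Alternatively, a full [re_mixture()] (overrides `mu`/`D`).
#' @return An object of class `group_parameters`.
#' @examples
#' sp <- marker_specs(marker_spec("alb", "gaussian"))
#' group_parameters(sp, mu = c(3.5, -0.01), D = diag(c(0.07, 1e-4)),
#'                  sigma = c(alb = 0.3))
#' @export
group_parameters <- function(specs, mu = NULL, D = NULL, sigma = numeric(0),
                             alpha = list(), mixture = NULL) {
  specs <- as_marker_specs(specs)
  lay <- re_layout(specs)
  if (is.null(mixture)) {
    if (is.null(mu) || is.null(D)) abort_argument("supply either mu and D, or a mixture")
    mixture <- re_mixture(1, list(as.numeric(mu)), list(D))
  }
  if (mixture$q != lay$q) {
    abort_structure(sprintf(
      "random-effects dimension %d does not match the layout dimension %d",
      mixture$q, lay$q))
  }
  gauss <- names(specs)[vapply(specs, function(s) s$family == "gaussian", logical(1))]
  if (!setequal(names(sigma), gauss)) {
    abort_structure("sigma must name exactly the gaussian markers")
  }
  if (length(sigma) && any(sigma <= 0)) abort_structure("residual SDs must be positive")
  for (s in specs) {
    p <- length(fixed_terms(s))
    a <- alpha[[s$name]] %||% numeric(0)
    if (length(a) != p) {
      abort_structure(sprintf("fixed coefficients for marker '%s' must have length %d",
                              s$name, p))
    }
  }
  structure(
    list(specs = specs, layout = lay, mixture = mixture,
         sigma = sigma[gauss], alpha = alpha),
    class = "group_parameters"
  )
}

#' @export
print.group_parameters <- function(x, ...) {
  cat(sprintf("<group_parameters> %d markers, q = %d, K = %d\n",
              length(x$specs), x$layout$q, x$mixture$K))
  invisible(x)
}

# K = 1 accessors (fitting and simulation presets use a single component).
params_mu <- function(params) params$mixture$means[[1L]]
params_D <- function(params) params$mixture$covariances[[1L]]

#' Assemble a random-effects covariance matrix from SDs and correlations
#'
#' Builds `D = diag(sd) %*% R %*% diag(sd)` where the correlation matrix R
#' has unit diagonal and the listed pairwise entries; pairs not listed are
#' taken as uncorrelated (0).
#'
#' @param sd Named vector of per-effect standard deviations (all positive).
#' @param corr Data frame with columns `a`, `b`, `corr` naming effect pairs
#'   and their correlation, or `NULL` for a diagonal matrix.
#' @param repair If the assembled matrix is not positive definite, clip its
#'   spectrum to the nearest positive-definite matrix instead of erroring.
#' @return A q x q covariance matrix with dimnames from `names(sd)`.
#' @examples
#' assemble_covariance(c(int = 1, slope = 2),
#'                     data.frame(a = "int", b = "slope", corr = 0.5))
#' @export
assemble_covariance <- function(sd, corr = NULL, repair = FALSE) {
  if (is.null(names(sd)) || any(!nzchar(names(sd)))) {
    abort_argument("`sd` must be a fully named vector")
  }
  if (any(sd <= 0) || any(!is.finite(sd))) abort_argument("all SDs must be positive")
  q <- length(sd)
  R <- diag(q)
  dimnames(R) <- list(names(sd), names(sd))
  if (!is.null(corr) && nrow(as.data.frame(corr))) {
    corr <- as.data.frame(corr)
    for (i in seq_len(nrow(corr))) {
      a <- as.character(corr$a[i]); b <- as.character(corr$b[i])
      r <- corr$corr[i]
      if (!a %in% names(sd) || !b %in% names(sd)) {
        abort_structure(sprintf("correlation names unknown effect pair (%s, %s)", a, b))
      }
      if (abs(r) > 1) abort_argument(sprintf("correlation |%g| > 1 for (%s, %s)", r, a, b))
      R[a, b] <- r
      R[b, a] <- r
    }
  }
  D <- diag(sd, q) %*% R %*% diag(sd, q)
  dimnames(D) <- dimnames(R)
  ev <- eigen((D + t(D)) / 2, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    if (!repair) {
      abort_structure(paste0(
        "assembled covariance is not positive definite (min eigenvalue ",
        signif(min(ev$values), 3),
        "); rerun with repair = TRUE for a nearest-PD spectral clip"))
    }
    vals <- pmax(ev$values, 1e-8 * max(ev$values))
    D <- ev$vectors %*% diag(vals, q) %*% t(ev$vectors)
    dimnames(D) <- list(names(sd), names(sd))
  }
  (D + t(D)) / 2
}
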
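# Classification evaluation: ROC construction, optimal-cutoff selection and
# confusion-matrix accuracy metrics, plus parameter-recovery summaries for
# simulation replicates.

check_two_classes <- function(labels) {
  u <- unique(labels)
  if (!all(labels %in% c(0, 1))) abort_argument("labels must be 0/1")
  if (length(u) < 2L) {
    abort_degenerate("both classes must be present to evaluate classification")
  }
}

#' ROC curve over all achievable cutoffs
#'
#' A patient is called positive when their score strictly exceeds the
#' cutoff. Cutoffs are placed at every distinct score plus -Inf and +Inf
#' sentinels, so the curve contains every achievable
#' (sensitivity, specificity) pair.
#'
#' @param scores Numeric scores (e.g. positive-group probabilities).
#' @param labels Binary labels, 1 = positive class.
#' @return A tibble of class `loda_roc` with columns `cutoff`,
#'   `sensitivity`, `specificity`, ordered by cutoff.
#' @export
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) abort_argument("lengths differ")
  check_two_classes(labels)
  cuts <- c(-Inf, sort(unique(scores)), Inf)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  sens <- vapply(cuts, function(c) sum(scores > c & labels == 1) / n_pos, numeric(1))
  spec <- vapply(cuts, function(c) sum(scores <= c & labels == 0) / n_neg, numeric(1))
  structure(tibble(cutoff = cuts, sensitivity = sens, specificity = spec),
            class = c("loda_roc", class(tibble())))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC polygon; exactly equal to the
#' Mann-Whitney concordance probability (ties counted half).
#'
#' @inheritParams roc_curve
#' @return The AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  check_two_classes(labels)
  roc <- roc_curve(scores, labels)
  fpr <- 1 - roc$specificity
  o <- order(fpr, roc$sensitivity)
  x <- fpr[o]; y <- roc$sensitivity[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Cutoff closest to the top-left ROC corner
#'
#' Returns the cutoff minimising the Euclidean distance
#' `sqrt((1 - sensitivity)^2 + (1 - specificity)^2)` to the ideal
#' (0, 1) corner; ties are broken toward the smaller cutoff.
#'
#' @param roc A [roc_curve()] result.
#' @return The optimal cutoff (a scalar).
#' @export
optimal_cutoff <- function(roc) {
  if (!nrow(roc)) abort_argument("empty ROC curve")
  d <- sqrt((1 - roc$sensitivity)^2 + (1 - roc$specificity)^2)
  best <- which(d == min(d))
  min(roc$cutoff[best])
}

#' Classification accuracy metrics at a cutoff
#'
#' Confusion-matrix summaries with "positive iff score > cutoff":
#' sensitivity, specificity, proportion correctly classified (PCC), AUC
#' (cutoff-free), positive and negative predictive values. PPV/NPV with an
#' empty denominator are reported as `NA`, not 0.
#'
#' @inheritParams roc_curve
#' @param cutoff Probability cutoff.
#' @return A one-row tibble: `cutoff`, `sensitivity`, `specificity`, `pcc`,
#'   `auc`, `ppv`, `npv`.
#' @export
metrics_at_cutoff <- function(scores, labels, cutoff) {
  check_two_classes(labels)
  pos <- scores > cutoff
  tp <- sum(pos & labels == 1); fn <- sum(!pos & labels == 1)
  fp <- sum(pos & labels == 0); tn <- sum(!pos & labels == 0)
  tibble(
    cutoff = cutoff,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    pcc = (tp + tn) / length(labels),
    auc = roc_auc(scores, labels),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

#' Parameter recovery across simulation replicates
#'
#' Aggregates per-replicate posterior summaries against the generating
#' truth: bias (mean posterior mean minus truth), across-replicate SD of
#' the posterior means, MSE of the posterior means, and coverage (fraction
#' of replicates whose credible interval contains the truth).
#'
#' @param summaries Tibble of per-replicate [posterior_summary()] rows with
#'   an added `replicate` column (`term`, `estimate`, `conf.low`,
#'   `conf.high` required).
#' @param truths Tibble with columns `term` and `truth`.
#' @return A tibble with one row per parameter: `term`, `truth`,
#'   `estimate` (mean posterior mean), `sd`, `bias`, `mse`, `coverage`.
#' @export
recovery_summary <- function(summaries, truths) {
  missing_terms <- setdiff(truths$term, unique(summaries$term))
  if (length(missing_terms)) {
    abort_structure(paste0("no replicate summaries for parameter(s): ",
                           paste(head(missing_terms, 3), collapse = ", ")))
  }
  dplyr::inner_join(summaries, truths, by = "term") |>
    dplyr::group_by(.data$term, .data$truth) |>
    dplyr::summarise(
      est_mean = mean(.data$estimate),
      est_sd = if (dplyr::n() > 1) sd(.data$estimate) else 0,
      bias = mean(.data$estimate) - .data$truth[1L],
      mse = mean((.data$estimate - .data$truth)^2),
      coverage = mean(.data$conf.low <= .data$truth &
                        .data$truth <= .data$conf.high),
      .groups = "drop"
    ) |>
    dplyr::rename(estimate = "est_mean", sd = "est_sd") |>
    dplyr::arrange(match(.data$term, truths$term))
}

#' Plot an ROC curve
#'
#' @param object A [roc_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.loda_roc <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}
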
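# ROC construction, cutoff selection, accuracy metrics, recovery summaries.

# brute-force reference: sensitivity/specificity at a cutoff by counting
ref_sens_spec <- function(scores, labels, cut) {
  c(sens = sum(scores > cut & labels == 1) / sum(labels == 1),
    spec = sum(scores <= cut & labels == 0) / sum(labels == 0))
}

test_that("the ROC curve enumerates every achievable operating point", {
  scores <- c(0.9, 0.4, 0.65, 0.4, 0.2, 0.75)
  labels <- c(1, 0, 1, 1, 0, 0)
  roc <- roc_curve(scores, labels)
  expect_equal(roc$cutoff, c(-Inf, sort(unique(scores)), Inf))
  for (i in seq_len(nrow(roc))) {
    ref <- ref_sens_spec(scores, labels, roc$cutoff[i])
    expect_equal(roc$sensitivity[i], ref[["sens"]])
    expect_equal(roc$specificity[i], ref[["spec"]])
  }
  # sentinels: everything positive / everything negative
  expect_equal(roc$sensitivity[1], 1)
  expect_equal(roc$specificity[1], 0)
  expect_equal(roc$sensitivity[nrow(roc)], 0)
  expect_equal(roc$specificity[nrow(roc)], 1)
  expect_error(roc_curve(scores, rep(1, 6)), class = "loda_error_degenerate")
})

test_that("perfectly separated and constant scores give the expected curves", {
  roc <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 1))
  roc_flat <- roc_curve(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))
  expect_true(all((roc_flat$sensitivity == 1 & roc_flat$specificity == 0) |
                    (roc_flat$sensitivity == 0 & roc_flat$specificity == 1)))
})

test_that("optimal cutoff minimises distance to the top-left corner", {
  scores <- c(0.05, 0.15, 0.3, 0.35, 0.5, 0.55, 0.7, 0.8, 0.9, 0.95)
  labels <- c(0, 0, 0, 1, 0, 1, 1, 0, 1, 1)
  roc <- roc_curve(scores, labels)
  copt <- optimal_cutoff(roc)
  # exhaustive scan oracle
  d <- sqrt((1 - roc$sensitivity)^2 + (1 - roc$specificity)^2)
  expect_equal(copt, min(roc$cutoff[d == min(d)]))
  d_at <- function(cut) {
    r <- ref_sens_spec(scores, labels, cut)
    sqrt((1 - r[["sens"]])^2 + (1 - r[["spec"]])^2)
  }
  expect_true(all(d_at(copt) <= vapply(roc$cutoff, d_at, numeric(1)) + 1e-12))
  # perfect separation: distance zero
  roc_p <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  co_p <- optimal_cutoff(roc_p)
  expect_equal(unname(ref_sens_spec(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), co_p)),
               c(1, 1))
  # symmetric tie broken toward the smaller cutoff
  roc_t <- roc_curve(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1))
  d_t <- sqrt((1 - roc_t$sensitivity)^2 + (1 - roc_t$specificity)^2)
  ties <- roc_t$cutoff[d_t == min(d_t)]
  expect_gt(length(ties), 1)
  expect_equal(optimal_cutoff(roc_t), min(ties))
})

test_that("metrics at a cutoff reproduce confusion-matrix arithmetic", {
  m <- metrics_at_cutoff(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unlist(m[c("sensitivity", "specificity", "pcc", "auc", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, pcc = 1, auc = 1, ppv = 1, npv = 1))
  # chance-level AUC for label-independent scores
  withr::with_seed(7, {
    sc <- runif(4000); lb <- rbinom(4000, 1, 0.5)
    expect_equal(metrics_at_cutoff(sc, lb, 0.5)$auc, 0.5, tolerance = 0.05)
  })
  # all-negative calls leave PPV undefined, not zero
  m2 <- metrics_at_cutoff(c(0.1, 0.2, 0.3, 0.4), c(0, 0, 1, 1), 0.9)
  expect_true(is.na(m2$ppv))
  expect_equal(m2$npv, 0.5)
})

test_that("trapezoidal AUC equals the Mann-Whitney concordance count", {
  scores <- c(0.1, 0.4, 0.4, 0.55, 0.62, 0.62, 0.8, 0.93)
  labels <- c(0, 0, 1, 0, 1, 0, 1, 1)
  conc <- 0
  for (i in which(labels == 1)) {
    for (j in which(labels == 0)) {
      conc <- conc + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  expect_equal(roc_auc(scores, labels), conc / (sum(labels == 1) * sum(labels == 0)))
  # independent library oracle on a random vector
  skip_if_not_installed("pROC")
  withr::with_seed(11, {
    sc <- runif(60); lb <- rbinom(60, 1, 0.4)
    expect_equal(roc_auc(sc, lb),
                 as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                                direction = "<"))))
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(13, {
    sc <- runif(40); lb <- rbinom(40, 1, 0.5)
    a0 <- roc_auc(sc, lb)
    expect_equal(roc_auc(qlogis(sc), lb), a0)
    expect_equal(roc_auc(sc^3, lb), a0)
  })
})

test_that("label swapping exchanges sensitivity/specificity and PPV/NPV", {
  withr::with_seed(17, {
    sc <- runif(50); lb <- rbinom(50, 1, 0.5)
    m <- metrics_at_cutoff(sc, lb, 0.5)
    # swapped problem: positives are the old negatives, scores reversed
    m_sw <- metrics_at_cutoff(-sc, 1 - lb, -0.5)
    expect_equal(m_sw$sensitivity, m$specificity)
    expect_equal(m_sw$specificity, m$sensitivity)
    expect_equal(m_sw$ppv, m$npv)
    expect_equal(m_sw$npv, m$ppv)
  })
})

test_that("recovery summaries compute bias, MSE, SD and coverage", {
  truths <- tibble::tibble(term = "theta", truth = 2)
  exact <- tibble::tibble(replicate = 1:3, term = "theta", estimate = 2,
                          sd = 0.1, conf.low = 1.5, conf.high = 2.5)
  r <- recovery_summary(exact, truths)
  expect_equal(r$bias, 0)
  expect_equal(r$mse, 0)
  expect_equal(r$coverage, 1)
  delta <- 0.3
  two <- tibble::tibble(replicate = 1:2, term = "theta",
                        estimate = c(2 - delta, 2 + delta), sd = 0.1,
                        conf.low = c(1.9, 2.4), conf.high = c(2.1, 2.6))
  r2 <- recovery_summary(two, truths)
  expect_equal(r2$bias, 0)
  expect_equal(r2$mse, delta^2)
  expect_equal(r2$coverage, 0.5)
  expect_error(recovery_summary(exact, tibble::tibble(term = "other", truth = 1)),
               class = "loda_error_structure")
})

test_that("credible-interval coverage calibrates at the nominal level", {
  # posterior mean ~ N(truth, 1) with exact 95% intervals
  withr::with_seed(23, {
    n <- 500
    est <- rnorm(n)
    reps <- tibble::tibble(replicate = seq_len(n), term = "theta",
                           estimate = est, sd = 1,
                           conf.low = est - 1.96, conf.high = est + 1.96)
    r <- recovery_summary(reps, tibble::tibble(term = "theta", truth = 0))
    expect_lt(abs(r$coverage - 0.95), 4 * sqrt(0.95 * 0.05 / n))
  })
})
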
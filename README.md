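# loda — longitudinal discriminant analysis

`loda` classifies patients into prognostic groups from their longitudinal
histories of mixed-type clinical markers — continuous, count and binary —
for example predicting which liver-disease patients under surveillance
will die or need a transplant within a time horizon.

## The method

Separate **multivariate generalised linear mixed models** are fitted to
the patients of each prognostic group *g*. For marker *r*, observation
*j*:

    h_r^{-1}( E[Y_rj | b] ) = x_rj' α_r^g + z_rj' b,   b | g ~ Σ_k w_k N(μ_k^g, D_k^g)

with canonical links (identity / log / logit), residual SDs φ_r for
gaussian markers, and a random-effects vector *b* shared across markers
(random intercepts and slopes, correlated across markers). Fitting is
Bayesian (Metropolis-within-Gibbs, all conjugate blocks drawn exactly,
adaptive random-walk steps for the non-gaussian parts), with a single
normal component (K = 1) as in the benchmark analyses.

A new patient's posterior probability of membership in group *g* is, per
MCMC draw *m*,

    P_g^(m) = π_g f_g^(m)(y_new) / Σ_g' π_g' f_g'^(m)(y_new)

averaged over the retained draws, where the predictive density `f_g` is
one of three constructions:

| approach | f_g | focus |
|---|---|---|
| marginal | ∫ f(y \| b) f(b) db | group mean profile + total variability |
| conditional | f(y \| b̂) | observation density at the subject's estimate b̂ |
| random-effects | f(b̂) | subject's deviations vs. the group's deviation distribution |

Classification uses the argmax rule or a ROC-derived cutoff (closest
point to the top-left corner), evaluated with sensitivity, specificity,
PCC, AUC, PPV and NPV under leave-one-out cross-validation. A
synthetic-data module generates two benchmark scenarios (a mean-profile
contrast with 4 mixed-type markers, and a residual-variance contrast with
2 gaussian markers; 200 + 50 patients, 4 visits) and a study runner
replicates the whole pipeline and aggregates accuracy and
parameter-recovery tables.

## A worked example

```r
library(loda)
library(dplyr)

scn <- builtin_scenario("scenario2")     # residual-variance contrast
sim <- simulate_dataset(scn, seed = 42)  # 250 patients, long format

pred <- loocv_predict(sim, scn$specs, mcmc_config(profile = "fast"),
                      mode = "fit_once", seed = 11)

for (a in unique(pred$approach)) {
  sub <- filter(pred, approach == a)
  lab <- as.integer(sub$true_group == 1)
  m <- metrics_at_cutoff(sub$p_1, lab, optimal_cutoff(roc_curve(sub$p_1, lab)))
  cat(sprintf("%s: cutoff %.2f sens %.3f spec %.3f pcc %.3f auc %.3f\n",
              a, m$cutoff, m$sensitivity, m$specificity, m$pcc, m$auc))
}
#> marginal: cutoff 0.22 sens 0.940 spec 0.835 pcc 0.856 auc 0.942
#> conditional: cutoff 0.51 sens 0.960 spec 0.815 pcc 0.844 auc 0.941
#> random_effects: cutoff 0.28 sens 0.760 spec 0.685 pcc 0.700 auc 0.759
```

The two groups differ only in measurement-error size, which the marginal
and conditional densities can see (AUC ≈ 0.94) but the random-effects
density cannot (AUC ≈ 0.76 and highly variable across replicates) — the
random effects themselves are poorly estimable when residual error
dominates.

Fitted models are tidyverse-friendly: `tidy(fit)` returns posterior
means, SDs and HPD intervals per parameter, `glance(fit)` one-row chain
diagnostics, and `autoplot()` works on ROC curves and study results.

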
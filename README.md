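# graftnet

Stability selection of donor–recipient predictors of **death-censored kidney
graft failure** via cross-validated elastic-net Cox regression.

Transplant registries are small relative to the number of candidate
predictors, so `graftnet` operationalizes a transparent selection workflow
for survival data: impute missing covariates with iterative random forests,
fit the elastic-net-penalized Cox partial likelihood
(`-ℓ(β)/n + λ[α‖β‖₁ + (1−α)/2‖β‖₂²]`, Breslow ties, cyclic coordinate
descent over a pathwise λ grid), pick the penalty by K-fold cross-validation
scored with Harrell's concordance index under the one-standard-deviation
rule, repeat the cross-validation many times with fresh fold draws, and vote
in the variables selected in more than half of the repeats. The voted
predictors are refit in an ordinary Cox model (hazard ratios, Wald 95% CIs),
survival curves for covariate profiles come from the Breslow cumulative
baseline hazard, and the modelling assumptions are checked with the
Grambsch–Therneau scaled-Schoenfeld test and penalized-spline (df = 5)
log-linearity screens.

Because no public registry accompanies this class of study, the package
includes a first-class synthetic-cohort generator (`synthetic_config()`,
`simulate_cohort()`) that emulates an adult transplant cohort: realistic
covariate marginals, seven true proportional-hazards effects, a decreasing
Weibull baseline calibrated to 89% cohort five-year survival, an independent
death process, era-staggered administrative censoring, and per-variable
missingness at realistic rates. See the methods vignette
(`vignettes/graft-failure-risk-modelling.Rmd`) for the model, every default,
and the design decisions.

## Worked example

```r
library(graftnet)
cfg <- synthetic_config(n = 822, seed = 7)
sim <- simulate_cohort(cfg)                      # cohort with missingness
imp <- missforest_impute(sim$cohort, seed = 7)   # random-forest imputation
X   <- build_design_matrix(imp$table)            # 25 candidate predictors
oc  <- to_death_censored(imp$table)              # death-censored outcome

round(100 * curve_at(kaplan_meier(oc), c(1, 5, 10)), 1)
#> [1] 96.5 91.0 87.3

sel <- stability_select(X, oc, n_repeats = 50, K = 10, alpha = 0.95, seed = 7)
print(sel)
#> Stability selection: 50 repeats of 10 -fold CV (alpha = 0.95 , rule = se )
#>                  variable count voted
#>  recipient_years_dialysis    50  TRUE
#>                 donor_age    50  TRUE
#>                donor_male    50  TRUE
#>            donor_diabetes    50  TRUE
#>             recipient_age     0 FALSE
#>  ...                           (21 further candidates, none voted)

fit <- cox_fit(X[, sel$voted, drop = FALSE], oc)
print(fit)
#> Cox proportional-hazards fit (Breslow ties), n = 822 , events = 82
#>                             HR lower  upper        p
#> recipient_years_dialysis 1.076 1.019  1.136 0.008230
#> donor_age                1.024 1.007  1.041 0.006350
#> donor_male               0.472 0.303  0.736 0.000916
#> donor_diabetes           4.930 2.122 11.455 0.000208

round(harrell_c(drop(X[, sel$voted, drop = FALSE] %*% coef(fit)), oc), 3)
#> [1] 0.671
```

Reading the output: graft survival in this simulated cohort is 96.5% / 91.0%
/ 87.3% at 1 / 5 / 10 years; the vote keeps four predictors, all of which
carry true effects in the generator (the raw years-on-dialysis column stands
in for its near-collinear log transform — the expected behavior when the
elastic net meets a correlated pair); the refit hazard ratios have the right
signs and magnitudes (e.g. male donor protective, HR 0.47; donor diabetes
harmful); and the in-sample concordance is 0.671. Weakly informative columns
(donor hypertension, HLA mismatch at this event count of 82) drop out — the
vote trades sensitivity for stability by construction.

The whole workflow — filters, imputation, selection, refit, baseline and
profile curves, diagnostics, concordance — is orchestrated by
`run_full_pipeline()`, which emits CSV/JSON artifacts and a manifest from
which any run can be replayed exactly.

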
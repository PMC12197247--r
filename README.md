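# dvtmatch

Multi-method propensity matching, ensemble weighting and counterfactual
treatment-effect estimation for comparing combined
anticoagulation + venoprotective therapy (CAV: rivaroxaban + aescin) against
standard anticoagulation (SAT: rivaroxaban alone) in deep vein thrombosis
(DVT) cohorts.

Observational DVT cohorts comparing these regimens are heavily unbalanced
(roughly 7:1 in favor of standard therapy) and confounded: treated patients
differ at admission in coagulation status (APTT, TT), blood counts (WBC,
PLT) and gender. `dvtmatch` is for biostatisticians and health-economics
analysts who need the full workflow — outcome derivation, matching, method
weighting, counterfactual estimation, sensitivity analysis — as tested,
reusable, seed-reproducible R functions, plus a synthetic-cohort generator
with known injected effects for validating the estimators when the original
hospital data are unavailable.

## The method

Six outcomes are derived per admission: the improvement rate
**IPR = (Day-1 score − discharge score)/Day-1 score × 100** (percent), the
daily improvement rate **DIR = IPR/LOS**, the cost-effectiveness ratio
**CER = cost/score reduction** (CNY per point), the daily improvement cost
**DIC = cost/DIR**, the cost–LOS efficiency **CLE = CER/LOS**, and the
length of stay **LOS** (days). Records with zero score change are excluded
(the ratio metrics are undefined).

When the arm-size ratio exceeds 2:1, four 1:1 matching algorithms run on 17
baseline covariates: nearest-neighbour on the logit propensity score with a
0.2-SD caliper, Mahalanobis distance, exact optimal assignment (minimum
total |logit distance|, gender matched exactly, solved by dynamic program),
and a genetic search over diagonal covariate weights minimizing the maximum
post-match standardized mean difference (SMD).

Each matched dataset m is scored on five quality dimensions and combined
into ensemble weights

w_m ∝ 0.25·s(1/meanSMD) + 0.15·s(1/maxSMD) + 0.25·s(CV-R²) +
0.30·s(Rosenbaum robustness at Γ = 1.5) + 0.05·s(retention),

where s(·) normalizes each dimension to shares summing to one across
methods. Per outcome and method, a T-learner (arm-specific random forests)
yields individual effects ITE_i = ŷ₁(x_i) − ŷ₀(x_i) and their averages
ATE/ATT/ATC, cross-checked by a double-residual (residual-on-residual)
estimate; final estimates are the ensemble-weighted averages
Σ_m w_m τ̂_m. Rosenbaum bounds (Wilcoxon signed-rank statistic under
bounding sign probabilities p± = Γ/(1+Γ), 1/(1+Γ)) quantify robustness to
hidden bias over Γ ∈ [1, 2], and a thresholded (|r| > 0.3) Spearman
correlation network links baseline coagulation covariates to outcomes.

## Worked example

```r
library(dvtmatch)

params <- cohort_params(n_total = 396, seed = 42)   # study-like conditions
ground_truth(params, n_mc = 20000)
#> Ground-truth outcome effects (19642/20000 MC draws used, exclusion rate 0.018)
#>   metric   effect       se
#> 1 ipr       6.34  4.33e- 3
#> ...
#> 6 los       0.150 2.23e-18

report <- run_pipeline(pipeline_config(params = params, seed = 42))
#> [input] 396 records
#> [exclusions] 11 excluded, 385 retained
#> [matching] arm ratio 7.56 > 2: running four matching methods
#> [weights] genetic=0.173, mahalanobis=0.143, nearest_caliper=0.189, optimal_exact=0.495
#> [effects] 30 effect rows
#> [network] 18 edges

dplyr::filter(report$effects, outcome == "ipr")
#>   outcome method            ate   att   atc dr_effect
#> 1 ipr     genetic          6.35  6.82  5.89      6.17
#> 2 ipr     mahalanobis      5.85  6.22  5.49      6.81
#> 3 ipr     nearest_caliper  2.30  2.84  1.76      3.31
#> 4 ipr     optimal_exact    8.26  8.47  8.06      7.30
#> 5 ipr     weighted         6.46  6.80  6.12      6.28
```

The generator injected a true IPR effect of 6.34 percentage points (Monte
Carlo, after boundary truncation of the nominal 6.4); the ensemble-weighted
ATE on this cohort is 6.46 — the per-method estimates scatter (2.3–8.3 on
~48 matched pairs each) and the weighted average pools them. `ground_truth`
shows LOS truth exactly 0.15 days. `write_report(report, "out/")` serializes
every stage artifact (balance tables, quality scores, weights, the
30-row effect table, sensitivity curves, the network as GraphML) as plain
text; `plot_balance()`, `plot_weights()`, `plot_sensitivity()`,
`plot_ite()` and `plot_network()` give the standard figures.

The package also ships the published per-method reference estimates
(`reference_effects()`, `reference_weights()`) so the weighted-aggregation
layer can be exercised against printed weighted averages.

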
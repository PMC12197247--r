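---
title: "Ensemble-weighted propensity matching and counterfactual effects for DVT therapy comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-weighted propensity matching and counterfactual effects for DVT therapy comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Deep vein thrombosis (DVT) is routinely treated with a direct factor Xa
inhibitor (rivaroxaban). A combined regimen that adds a venoprotective agent
(aescin, from horse chestnut seed extract) is hypothesized to improve
symptom resolution and economic efficiency without extending
hospitalization. Observational hospital cohorts comparing the combined
regimen (CAV) with standard anticoagulation (SAT) are strongly unbalanced —
on the order of 350 standard-therapy admissions for every 50 combined-therapy
admissions — and treatment allocation is confounded with admission
coagulation status (APTT, TT), blood counts (WBC, platelets) and gender.

`dvtmatch` implements a complete causal-inference workflow for this setting:

1. **Outcome metrics.** From raw admission fields it derives six outcomes:
   the improvement rate IPR = (Day-1 score − discharge score)/Day-1 score ×
   100 (percent); the daily improvement rate DIR = IPR/LOS; the
   cost-effectiveness ratio CER = cost/absolute score reduction (CNY per
   point); the daily improvement cost DIC = cost/DIR; the cost–LOS
   efficiency CLE = CER/LOS; and the length of stay LOS (days). Records
   whose symptom score did not change are excluded — CER and DIC divide by
   the score reduction and are undefined there. Worsening (negative
   improvement) is retained; only the exact-zero case is removed.
2. **Multi-method matching.** When the arm-size ratio exceeds 2:1, four 1:1
   matching algorithms are run on 17 baseline covariates (age, gender,
   height, weight, Wells score, WBC, RBC, Hgb, PLT, HCT, PT, INR, APTT, TT,
   Fib, D-dimer, FDP).
3. **Ensemble weighting.** Each matched dataset is scored on five quality
   dimensions and the scores are combined into composite weights.
4. **Counterfactual estimation.** A T-learner (arm-specific random forests)
   produces individual treatment effects and ATE/ATT/ATC per outcome and
   method, with a double-residual estimate as a cross-check; per-method
   estimates are combined with the ensemble weights.
5. **Sensitivity and structure.** Rosenbaum bounds quantify robustness to
   unmeasured confounding across Γ ∈ [1, 2], and a thresholded correlation
   network links baseline covariates to outcomes.

Because the motivating hospital data are not publicly available, the package
ships a seeded synthetic-cohort generator with *known injected effects*, so
every stage is testable end-to-end and estimator calibration can be checked
against a Monte-Carlo ground truth.

## The synthetic cohort generator

`cohort_params()` defaults encode the study conditions of the motivating
cohort:

- **Size and imbalance**: 396 admissions with an expected treated fraction
  of 48/396. The intercept of the assignment model is calibrated so the
  expected CAV share matches this fraction.
- **Covariate marginals**: truncated normals for the continuous
  anthropometrics and labs, with locations at the published medians and
  scales at IQR/1.35 (the normal-theory conversion); Bernoulli gender
  (46% male); a discretized gamma (0.5-point grid) for the Wells score.
  Skew-tolerant families suffice because only medians and IQRs are
  reported for the reference cohort.
- **Confounding channel**: log-odds slopes on standardized APTT (−0.8),
  WBC (−0.35), PLT (−0.22), TT (+0.55) and male gender (+0.65), mirroring
  the significant arm imbalances observed in practice (treated patients
  present with shorter APTT, lower WBC/PLT, longer TT, more often male).
  All other slopes are zero.
- **Outcome models**: Day-1 score driven by Wells score and D-dimer;
  discharge score via a baseline improvement fraction (mean ≈ 55%)
  decreasing in platelet count; log-LOS increasing in Wells score and age;
  log-cost increasing in realized LOS, admission severity and APTT. Costs
  are log-normal — positive and right-skewed, as hospitalization costs are;
  no cost distribution is published, so the scale (≈ 21,000 CNY median) is
  a realistic choice. Because cost responds to APTT and the economic
  metrics divide cost by improvement, the generator reproduces the
  coagulation–economics correlation structure that the network stage is
  designed to detect.
- **Injected effects**: treatment shifts the discharge score by
  −0.064 × Day-1 score (an exact +6.4 percentage-point IPR effect per
  record, before truncation at the score boundaries), adds +0.15 days of
  LOS, and multiplies cost by exp(−0.15). A small rate (7/403) of records
  is forced to zero score change to exercise the exclusion rule.
- **Reproducibility**: a single integer seed feeds one hashed substream per
  record, so a record's draws are invariant to the presence of other
  records; cohorts serialize byte-identically for a fixed seed.

`ground_truth()` computes the implied average causal effect on each of the
six metrics by Monte-Carlo contrast of the two potential-outcome arms on
fresh covariate draws (both arms share noise, so a null configuration has
exactly zero effect). Under the defaults the IPR truth is ≈ 6.34 pp (the
nominal 6.4 minus a small truncation loss) and the LOS truth is exactly
0.15 days.

What the generator does **not** emulate: longitudinal trajectories,
missing data, site effects, and — by default — cross-covariate correlation
(an optional Gaussian-copula correlation matrix is available; independence
plus the confounding slopes is the shipped default, since the joint
covariate structure of the reference cohort is unpublished). Passing tests
on this generator therefore demonstrate estimator correctness under a
realistic but idealized data-generating process, not performance on any
particular hospital's records.

```{r}
library(dvtmatch)
params <- cohort_params(n_total = 396, seed = 1)
cohort <- generate_cohort(params)
ground_truth(params, n_mc = 20000)
```

## The matching algorithms

All four methods produce 1:1 pairs without replacement (the reference
analysis retains equal arm sizes throughout, and its pair counts imply no
reuse of controls). The propensity model is a main-effects logistic
regression of arm on the 17 covariates — continuous ones z-scored, gender
0/1 — the field-default specification; perfect separation falls back to a
lightly ridge-penalized fit.

- **Nearest neighbour with caliper** (`match_nearest_caliper()`): greedy on
  the logit propensity score, treated records in descending-score order
  (hardest to match first, the standard greedy heuristic), ties broken
  toward the smaller control id for determinism. The caliper default is
  0.2 SD of the logit score — the widely used Austin recommendation, since
  the reference analysis does not state its width. Tight calipers drop
  unmatched treated records, trading retention for balance.
- **Mahalanobis distance** (`match_mahalanobis()`): greedy on the
  Mahalanobis distance with the pooled within-arm covariance of the
  standardized covariates (ridge-regularized if near-singular; a diagonal
  variant is available).
- **Optimal with exact constraints** (`match_optimal_exact()`): exact
  minimum-total-|logit distance| assignment within strata of the
  exact-match variables (default gender — the method's published balance
  table shows an exact gender SMD of zero). Because the cost is a
  1-dimensional absolute difference, an optimal assignment is non-crossing
  after sorting, and a two-index dynamic program solves the assignment
  problem exactly in O(mn). Strata with fewer controls than treated are
  relaxed with a warning; all treated are retained whenever feasible.
- **Genetic matching** (`match_genetic()`): an evolutionary search over
  positive diagonal weights w for the distance
  d(x_t, x_c) = sqrt(Σ_j w_j (z_tj − z_cj)²). Each candidate induces a
  greedy match scored by post-match balance; fitness minimizes the maximum
  covariate SMD with mean SMD as tie-break (balance is the published
  evaluation criterion for this method; the loss function is otherwise an
  open choice). The equal-weights vector is always in the initial
  population, so the search can never return a worse match than unweighted
  Euclidean matching; the search is seeded and fully reproducible.

Balance is reported as absolute standardized mean differences:
|mean_t − mean_c| / sqrt((var_t + var_c)/2) for continuous covariates and
the proportion analogue for binary ones, with mean and maximum across the
17 covariates as summaries (`balance_report()`, `plot_balance()`).

## Ensemble weighting

`method_quality()` assembles, per matched dataset: mean and max post-match
SMD; the average out-of-fold R² of a random forest predicting each outcome
from the 17 covariates plus the arm indicator under 5-fold cross-validation
stratified by arm (negative values are legitimate and retained); the
Rosenbaum robustness — the fraction of the six outcomes keeping an
upper-bound p < 0.05 at Γ = 1.5; and the treated-arm retention fraction.

`composite_weight()` turns each dimension into a share across methods —
inverse SMD 1/(smd + ε), ε = 10⁻⁶, normalized to sum to one for the two
balance dimensions ("inversely proportional" is the stated direction; the
share normalization is this package's concrete choice, making every
dimension comparable on [0, 1]); CV-R² floored at zero then normalized
(a negative share would break the convexity of the composite); robustness
and retention normalized directly — and combines them with the fixed
dimension weights 25% (mean SMD), 15% (max SMD), 25% (predictive R²), 30%
(robustness), 5% (retention), renormalizing the composite to sum to one.
The dimension weights are constants of the method, exposed in
configuration. The resulting weights are sum-to-one, permutation
equivariant, scale-free in a common SMD rescaling, and monotone in each
method's balance.

## Rosenbaum bounds

For matched pairs with hidden bias at most Γ (the odds of treatment within
a pair differ by at most a factor Γ), the sign of each nonzero pair
difference is bounded by Bernoulli probabilities p± with
p⁺ = Γ/(1+Γ), p⁻ = 1/(1+Γ). With T the Wilcoxon signed-rank statistic over
nonzero differences (mid-ranks for ties) and r_s their ranks,

- E±[T] = p± Σ r_s, Var±[T] = p±(1−p±) Σ r_s²,
- p_upper = 1 − Φ((T − E⁺)/√Var⁺), p_lower analogously with p⁻.

At Γ = 1 both bounds equal the standard one-sided normal-approximation
signed-rank p-value. Tests are one-sided in the direction of hypothesized
benefit (IPR, DIR, CLE positive; DIC negative, tested after a sign flip)
and two-sided (double the smaller one-sided bound) for LOS and CER, where
no direction is presumed.

**Accuracy of the normal approximation.** The package deliberately uses the
plain normal approximation (field practice) rather than exact tails. An
exhaustive comparison against the exact bounding distribution (all
achievable T values, Γ ∈ {1, 1.25, 1.5, 2}) shows worst-case absolute
deviations from the strict exact tail of 0.093 at n = 5 pairs shrinking to
0.037 at n = 12; against the mid-tail (half weight on the observed atom —
the quantity an uncorrected normal approximation actually estimates) the
worst cases are 0.038 at n = 5 and 0.021 at n = 12. Bounds at such small
pair counts should therefore be read as approximations good to a few
percentage points of probability; from a few dozen pairs upward the error
is negligible.

`attenuated_effect()` supplies a Γ-indexed point-estimate bound: the
largest shift τ at which the upper-bound p-value of the centered
differences crosses 0.5, found by bisection (tolerance 10⁻⁸ of the
difference range). At Γ = 1 this is the Hodges–Lehmann estimate (median of
Walsh averages); for Γ > 1 it shrinks conservatively toward zero.
`sensitivity_sweep()` evaluates both bounds and the attenuated effect on a
grid (default 1.0 to 2.0 by 0.1) and asserts the Γ-monotonicity of the
bounds on every run.

## Counterfactual effects

`t_learner()` fits one random-forest regression per arm (500 trees by
default, default depth and mtry, impurity importance, one thread and a
fixed seed for bit-reproducibility — defaults favor reproducibility over
tuning) and predicts both potential outcomes for every matched record:
ITE_i = ŷ₁(x_i) − ŷ₀(x_i). `treatment_effects()` averages ITEs over all
records (ATE), treated (ATT) and controls (ATC), so
ATE = (n_t·ATT + n_c·ATC)/(n_t + n_c) holds exactly. Only the 17 baseline
covariates enter the outcome models — no post-treatment variables.

`double_residual()` is the cross-check: out-of-fold (5-fold, arm-stratified)
forest predictions of the outcome and of the treatment indicator from the
covariates; the effect is the least-squares slope of outcome residuals on
treatment residuals, through the origin by default (both residual vectors
are mean-zero up to fold noise; an intercept variant is a flag).

`weighted_aggregate()` combines per-method estimates with the ensemble
weights; the same weights aggregate ATE, ATT, ATC and the double-residual
column. `effect_table()` produces the full 6 outcomes × (4 methods +
weighted) table.

## Correlation network

`correlation_matrix()` uses Spearman correlation by default — admission
labs and ratio-type outcomes are skewed, making rank correlation the safer
default; Pearson is a flag. `build_network()` keeps edges with |r|
strictly above the threshold (default 0.3), classes nodes as baseline or
outcome and edges by endpoint classes, sizes baseline nodes by their
summed normalized variable importance across outcomes (outcome nodes by
degree — no formula for outcome-node importance is published, degree is
this package's choice), and exports GraphML. Both the full post-exclusion
cohort and the top-weighted matched sample are supported as the
correlation scope (the reference analysis does not state which it used;
the full cohort is the default).

## Pipeline and reproducibility

`run_pipeline(pipeline_config(...))` executes exclusions → outcomes →
matching (iff the arm ratio exceeds 2:1, implemented literally; otherwise a
single-sample analysis with a logged skip) → quality → weights → effects →
sensitivity → network, and `write_report()` serializes every artifact as
plain text (CSV/JSON/GraphML). Identical (config, seed) pairs produce
byte-identical reports; every random-forest fit, fold assignment, and the
genetic search derive their seeds from the single master seed via the same
hashed-substream scheme as the generator.

## Validation strategy and problem sizes

The test suite validates each operation against independent oracles: closed
forms (2×2 logistic slope, SMD hand computations, Spearman's rank formula),
brute-force enumeration (tiny assignment problems, 2ⁿ sign configurations
for the Rosenbaum bounding distribution, Walsh-average medians, grid search
over genetic weights), and generative recovery on cohorts with known
injected effects. Estimator calibration is checked on 20 seeded cohorts of
n = 800 with a +6.4 pp injected IPR effect under confounded assignment
(ensemble-weighted ATE mean within 1.5 pp of the Monte-Carlo truth, and a
null configuration within 1 pp of zero); the recovery suite uses reduced
search and forest budgets (genetic 4 × 10, 120–200 trees) — enough for the
estimators to stabilize at these sample sizes while keeping the suite
fast. End-to-end determinism is asserted byte-for-byte at n = 400.

## Known limitations

- Confidence intervals for the aggregated effects are out of scope (no
  construction is published for the reference estimates; none is invented).
- The Rosenbaum normal approximation is inaccurate below ~10 pairs (see
  the worst-case analysis above); an exact option is deliberately not the
  default, matching field practice.
- Random-forest T-learners on ~50 matched pairs carry nontrivial
  Monte-Carlo spread; single-cohort weighted ATEs at n ≈ 400 scatter with
  an SD of roughly 1.5 pp around the truth for IPR. Replicate means (as in
  the acceptance script) are the stable quantity.
- The genetic search optimizes balance only through a diagonal metric; no
  claim of equivalence with any specific external genetic-matching
  implementation's tie-breaking is made.
- The ensemble's published composite weights are not numerically
  recoverable without the original hospital data; the package verifies the
  weighting *formula* (algebraic properties, hand-computed examples) and
  the aggregation layer against the published weighted rows instead.
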
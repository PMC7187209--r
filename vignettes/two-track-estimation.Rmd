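---
title: "Two-track treatment-effect estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-track treatment-effect estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmpool)
```

kmpool estimates the effect of adjuvant chemotherapy on disease-free
survival (DFS) in Stage II colon cancer along two evidence tracks — pooled
randomized trials and a registry-style observational cohort — and tests
whether the two tracks agree. This vignette explains the models, the
numerical choices, and the points where the design was genuinely open.
Times are in months throughout; "5-year DFS" means `S(60)`.

## 1. Reconstructing patient-level data from published aggregates

Published trials rarely share patient-level data; they print a Kaplan–Meier
curve and a numbers-at-risk table. The reconstruction module inverts that
reporting, in the spirit of the curve-fitting family of methods that
combine both pieces of evidence.

**Preprocessing.** Digitized coordinates are manual readings: survival can
exceed 1, wobble upwards, or repeat a time. `preprocess_curve()` clips to
`[0,1]`, collapses duplicate times to their lowest reading, anchors
`S(0) = 1`, and restores monotonicity with a running minimum. The running
minimum (rather than, say, isotonic regression) never *raises* a reading,
so a single upward blip is corrected without disturbing its neighbours.

**Interval counts.** Let `n_j` be the number at risk at risk-table time
`T_j` and `S(·)` the digitized curve, read at risk-table times by
last-observation-carried-forward (the step-function semantics of a KM
curve). For each interval the decline `n_j − n_{j+1}` must decompose into
`d_j` events and `c_j` censorings. We assume censoring is spread uniformly
through the interval and approximate its effect by removing `c_j/2` from
the risk set before the events act, so a candidate split implies a
conditional survival `(n_j − c_j/2 − d_j)/(n_j − c_j/2)`. The split is
chosen by exhaustive search over the (at most `n_j + 1`) integer pairs —
the search space is tiny, so the brute force *is* the implementation, and
the test suite checks it against an independently written enumeration. Ties
in the objective resolve toward fewer events, a conservative choice that
only triggers in degenerate inputs. If the risk table *rises* (a reporting
inconsistency), the interval's counts are clipped to zero, a warning is
raised, and the discrepancy shows up in the fidelity report — the risk
table is never silently renormalized.

**Placement.** Events are placed on the digitized step times inside the
interval, apportioned proportionally to the step drops with
largest-remainder rounding; this preserves the visible curve shape, which
interval midpoints would blur. Censorings are placed at evenly spaced times
strictly inside the interval (e.g. two censorings on `[12, 24)` sit at 16
and 20). Patients still at risk after the last risk-table time are
allocated events from residual curve drops, the remainder being
administratively censored at the curve's end. The output always contains
exactly `n_1` records.

**When is the round trip exact?** With a noiseless curve read at the event
times and no censoring interior to the intervals, the product-limit factors
inside an interval telescope to `(n_j − d_j)/n_j`, the search recovers the
true `(d_j, c_j)` (the implied ratio is strictly decreasing in `d`), and
the reconstructed KM equals the source KM at every risk-table time —
exactly, and the tests assert that. With interior censoring the reported
conditional ratio is generally not representable by any integer split, so
exactness gives way to a tolerance: the suite checks a maximum KM deviation
of 0.02 at risk-table times in at least 95% of noisy replicates
(digitization noise SD 0.005, 500 patients per arm). For the same reason
the 3-sigma envelope on digitization noise is asserted as a 95% per-replicate
property, not a hard bound — Gaussian tails across a multi-point grid exceed
any fixed multiple of sigma eventually.

## 2. Trial-track survival models

The pooled analyses concatenate, per trial, the two arms being compared, so
each trial contributes only its own randomized contrast. With treatment
indicator `x` the hazard is `h(t|x) = h0(t) exp(βx)`; `exp(β)` is the
hazard ratio (HR), with HR ≤ 0.80 conventionally read as clinically
meaningful in this disease setting.

* **Ties.** Efron's correction is the default: reconstruction stacks events
  on digitized step times, so ties are the rule, and Efron is markedly less
  biased than Breslow under heavy ties. Breslow is available by flag.
* **Multilevel model.** Between-trial heterogeneity enters as a per-trial
  random intercept on the log hazard, `b_i ~ N(0, τ²)` (log-normal
  frailty), fitted by penalized partial likelihood via
  `survival::coxph(... + frailty.gaussian(trial))`. The reported standard
  error comes from the penalized information; the variance now carries both
  the uncertainty of the treatment effect and that of the random effect, so
  it is never smaller than the plain fit's — the suite verifies this on
  simulated heterogeneous trials. `theta = 0` is implemented as the exact
  mathematical reduction to the plain fit (all intercepts pinned at zero),
  and a single-trial input falls back to the plain fit with a warning
  because τ² is then unidentifiable.
* **No covariates** are offered in the trial track: reconstruction cannot
  recover covariates from a marginal curve, and pretending otherwise would
  be false precision.
* **Parametric companion.** `weibull_ph_fit()` is a maximum-likelihood
  Weibull proportional-hazards fit (`flexsurv`, `weibullPH`
  parameterization, exponential at shape 1). It is a generic parametric
  check on the semiparametric estimate — agreement within 0.02 on the log
  HR is asserted on correctly specified simulations — not a replication of
  any particular published parametric analysis.
* **Confidence intervals** are 95% Wald on the log-HR scale everywhere;
  convergence uses the `survival` Newton–Raphson with a tightened
  tolerance (`eps = 1e-10`). A monotone partial likelihood (complete
  separation of risk sets) is detected and raised as a diagnostic error
  rather than silently returning a huge coefficient.

## 3. Registry-track propensity corrections

The cohort model treats assignment to adjuvant treatment as logistic in six
pretreatment covariates: sex, age, pT stage, number of evaluated lymph
nodes (< 10 vs ≥ 10), differentiation grade, and tumor site. AIC backward
elimination from the full candidate set selects the model; pairwise
covariate-by-covariate interactions can be included in the candidate set
(off by default — with 1,947 patients and 114 treated, 15 interaction terms
invite overfitting, and the identity of the "interactions" in the emulated
analysis is ambiguous: an interaction *with treatment* cannot enter a model
whose outcome is treatment). Perfect separation aborts with the offending
covariate named.

Three corrections consume the fitted score `e(x)`:

* **Matching** — greedy 1:1 nearest neighbour without replacement, treated
  patients processed in descending score order. "Caliper 0" means exact
  score equality (tolerance 1e-10), which is attainable because registry
  covariates are categorical and age is recorded in whole years, so
  covariate patterns repeat; the wide caliper is 0.2 SD of the logit score,
  with distance measured on the logit scale. Unmatched treated patients are
  dropped and counted. The effect model on the matched sample is a
  multivariate Cox fit with a pair-clustered robust variance.
* **Weighting** — stabilized ATE weights, `P(T=1)/e(x)` for treated and
  `P(T=0)/(1−e(x))` for controls, after truncating scores to
  `[0.01, 0.99]`; stabilization keeps the mean weight near 1 and the sum
  near `n`. The weighted multivariate Cox fit uses a robust sandwich
  variance, since the model-based variance is anti-conservative under
  weighting.
* **Stratification** — quintiles of the score over the whole cohort;
  per-stratum multivariate Cox fits are pooled by fixed-effect
  inverse-variance averaging of the log HRs (the pooled value therefore
  always lies inside the per-stratum range). Strata with no treated
  patients, no events, or no treatment contrast are excluded with a
  warning; constant scores are rejected outright because quantile bins
  would be degenerate.

All multivariate effect models share one covariate set — age, pT stage,
lymph nodes, site, differentiation — so the variants are comparable; the
naive estimate is deliberately unadjusted.

## 4. Comparing the tracks

`interaction_test()` is the z-test on the difference of two independent log
HRs, `z = (β₁ − β₂)/√(se₁² + se₂²)`. The default α is 0.10 for the
RCT-vs-registry comparison — lenient on purpose, because the registry
estimates are imprecise and a stricter level would make "no difference
detected" nearly automatic — and 0.05 elsewhere.
`homogeneity_test()` compares 5-year DFS across pooled arms pairwise on the
complementary log-log scale, `log(−log S(60))`, with delta-method variances
from the Greenwood standard errors. The cloglog scale was an open choice
(the emulated analysis does not state one); it respects the `[0,1]` range
and stabilizes variance where survival is high. The pairwise p-values are
reported unadjusted, with the number of comparisons attached.

## 5. What the synthetic generators emulate — and what they do not

`simulate_trial_ipd()` draws exponential (default) or Weibull event times
under proportional hazards with a per-trial `N(0, sd²)` log-hazard
intercept — the generating counterpart of the frailty estimator. Defaults
encode the emulated trial world: control-arm rate `−log(0.77)/60` per month
(5-year DFS 0.77, the centre of the 0.74–0.80 range of the pooled control
arms), true HR 0.8, 7 trials, trial SD 0.2, administrative cut-off 72
months, light random censoring (0.002/month). The exponential default keeps
closed-form checks available (e.g. rate 0.01155/month gives a 60-month
median exactly).

`simulate_registry()` draws the six covariates from the emulated registry
marginals (age 70.9 ± 11.0 years, pT4 10.0%, < 10 nodes 53.9%, right-sided
60.2%, poor differentiation 16.7%), assigns treatment by a logistic model,
and draws DFS from a proportional-hazards outcome model. Design notes:

* The assignment **intercept is not a free parameter**: it is calibrated by
  root finding so the expected treated fraction hits the target (default
  5.9%).
* The default assignment coefficients were back-calculated analytically
  (exponential tilting of each marginal) so the treated subgroup reproduces
  the emulated contrasts — about ten years younger, pT4 ≈ 34%,
  < 10 nodes ≈ 66%, poor differentiation ≈ 30%. Because the tumor-severity
  effects outweigh the protective age contrast in the outcome model, the
  naive HR under a null treatment effect is biased upward — the
  confounding-by-indication signature the corrections must undo.
* The registry does not report a male fraction in the table we emulate;
  0.55 is used as a typical figure for colon-cancer cohorts. Likewise the
  cohort's DFS event count is unreported, so the baseline outcome hazard
  (0.0024/month) was set once so that whole-cohort 5-year DFS is roughly
  0.75.
* Ages are integers, as registries record them — which is also what makes
  exact-score matches possible.

What the generators do **not** emulate: non-proportional hazards, competing
risks (death without recurrence vs recurrence), covariate-dependent or
informative censoring, unmeasured confounders (e.g. performance status),
overall survival, and time-varying treatment. Passing tests therefore show
that the estimators recover known truths *under their own assumptions*;
they cannot show robustness to violations real data may exhibit.

## 6. Reproducibility and problem sizes

Every stage draws from a named sub-stream derived deterministically from
one global seed (`substream_seed()`), so whole runs are byte-identical and
stages can be re-run independently; `run_pipeline()` records the seed and
all warnings in its JSON log, because clipped intervals and dropped strata
silently change estimates and deserve an audit trail.

The simulation-based checks in the test suite use problem sizes chosen to
make Monte-Carlo error small relative to the asserted margins while keeping
the suite quick on a single CPU: 7 trials × 2,000 patients/arm × 100
replicates for frailty recovery, 100 replicates for the
aggregate–reconstruct–refit loop (mean absolute log-HR error below 0.05),
200 replicates of n = 5,000 cohorts for naive-bias direction and ≥ 90% CI
coverage of the null by all three corrections, n = 50,000 for the marginal
calibration, and 1,000 null replicates for the interaction test's empirical
size at α = 0.10.

## 7. Known limitations

* The half-interval censoring correction is an approximation; when censoring
  is heavy and uneven within intervals the reconstructed event counts can be
  off by small integers even at zero digitization noise.
* The frailty variance τ² is weakly identified with few trials; with 7
  trials its estimate is noisy, and the penalized-likelihood standard error
  of β widens only modestly when arms are balanced within trials.
* Greedy matching is order-dependent by construction; optimal (minimum
  total distance) matching is out of scope.
* Inverse-variance pooling of stratum log HRs assumes a common effect
  across strata; it is the conventional fixed-effect choice, not a test of
  effect modification.
* The interaction test treats the two tracks as independent, which holds
  here by construction but would not if the same patients informed both.
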
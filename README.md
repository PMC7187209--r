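# kmpool

Two-track estimation of adjuvant treatment effects on disease-free survival
(DFS) in Stage II colon cancer — and a framework for asking whether evidence
synthesized from randomized trials agrees with evidence from a real-world
registry.

The package is aimed at biostatisticians and epidemiologists who need to

1. **reconstruct pseudo individual-patient data (IPD)** from what published
   trials actually report — a digitized Kaplan–Meier curve plus its
   numbers-at-risk table;
2. **pool** the reconstructed arms across trials and estimate a hazard ratio
   (HR) with a plain Cox model and with a **multilevel (trial-frailty) Cox
   model**;
3. estimate the same effect in an **observational cohort** with strong
   confounding by indication, using propensity-score **matching**,
   **inverse-probability weighting** and **stratification**;
4. **compare the two tracks** with an interaction test on the difference of
   log hazard ratios.

A synthetic-data module simulates both data worlds with known ground truth —
multi-trial survival data with a between-trial random effect, and a
registry-style cohort whose covariate marginals, treated fraction (≈ 5.9%)
and confounding structure mimic a national cancer-registry sample — so the
entire pipeline is testable without access to restricted data.

## The statistics in brief

**Reconstruction.** For each interval `[T_j, T_{j+1})` between risk-table
times, the observed decline in the number at risk `n_j − n_{j+1}` is split
into events `d_j` and censorings `c_j` by exhaustive integer search, choosing
the pair whose implied conditional survival

```
(n_j − c_j/2 − d_j) / (n_j − c_j/2)
```

(censoring spread uniformly through the interval) best matches the reported
ratio `S(T_{j+1})/S(T_j)`. Events are then placed on the digitized step times
(largest-remainder apportionment over step sizes), censorings evenly inside
the interval, yielding one record per patient at risk at time 0.

**Trial track.** With treatment indicator `x` the Cox model is
`h(t|x) = h0(t) exp(βx)`; the pooled analyses add a per-trial random
intercept `b_i ~ N(0, τ²)` on the log hazard,
`h(t|x, trial i) = h0(t) exp(βx + b_i)`, fitted by penalized partial
likelihood (Efron tie handling — reconstructed event times are tie-heavy by
construction).

**Real-world track.** The propensity score `e(x) = P(treated | covariates)`
comes from a logistic model with AIC backward selection. Corrections:
1:1 greedy nearest-neighbour matching without replacement (caliper 0 = exact
score equality, or 0.2 SD of the logit score), stabilized ATE weights
`P(T=t)/e(x)` resp. `P(T=t)/(1−e(x))`, and quintile stratification with
fixed-effect inverse-variance pooling of per-stratum log HRs.

**Comparison.** For two independent estimates,
`z = (β₁ − β₂) / √(se₁² + se₂²)`, two-sided normal p, significance threshold
0.10.

## Worked example

Reconstruct a trial arm from a bundled (synthetic, noisy) digitized curve and
risk table:

```r
library(kmpool)

curve <- read_curve_csv(system.file("extdata", "synthetic_curve_control.csv",
                                    package = "kmpool"))
risk  <- read_risk_csv(system.file("extdata", "synthetic_risk_control.csv",
                                   package = "kmpool"))
rec <- reconstruct_arm(curve, risk, arm = "control", trial_id = "demo")
rec
#> <km_reconstruction> 250 patients (57 events, 193 censored)
#>   max |KM deviation| at risk-table times: 0.002768
#>   max |at-risk difference|: 3

km_at(km_estimate(rec$ipd), 60)
#> # A tibble: 1 × 3
#>    time survival std_err
#>   <dbl>    <dbl>   <dbl>
#> 1    60    0.794  0.0266
```

The reconstruction reproduces the input curve to within 0.003 at every
risk-table time and its implied at-risk counts to within 3 patients; 5-year
DFS on the reconstructed arm is 0.794 (Greenwood SE 0.027).

The whole two-track pipeline from one seed:

```r
res <- run_pipeline(list(seed = 1))
res$summary
#> # A tibble: 7 × 6
#>   model                                            hr ci_lower ci_upper   p_value comparison_p
#> 1 Survival model (pooled trials)                0.824    0.747    0.908 0.0000970    NA
#> 2 Multilevel survival model (pooled trials)     0.823    0.747    0.907 0.0000914    NA
#> 3 Naive survival model (registry)               1.503    1.114    2.029 0.00766      0.000179
#> 4 PS matching - caliper 0 (registry)            1.154    0.642    2.073 0.632        0.265
#> 5 PS matching - caliper 0.2 SD logit (registry) 1.033    0.679    1.569 0.881        0.301
#> 6 PS inverse weighting (registry)               1.189    0.748    1.890 0.464        0.128
#> 7 PS stratification (registry)                  1.122    0.812    1.552 0.485        0.0723
```

Read bottom to top: the trial track recovers the simulated true HR of 0.8;
in the registry track the unadjusted ("naive") model is badly biased by
confounding by indication (HR 1.50 although the simulated treatment effect
is null), and all three propensity corrections pull the estimate back to
≈ 1. The last column is the interaction-test p-value against the multilevel
trial-track estimate.

`tidy()`, `glance()` and `autoplot()` methods are available for the fitted
objects, and `plot_effect_forest()` draws the summary as a forest plot.

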
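test_that("null treatment assignment yields a near-constant score", {
  cfg <- registry_sim_config(
    n = 20000, seed = 61,
    assignment_coefficients = c(age = 0, t4 = 0, nodes_lt10 = 0,
                                diff_poor = 0, right = 0, male = 0),
    target_treated_fraction = 0.2
  )
  cohort <- simulate_registry(cfg)
  ps <- fit_propensity(cohort, selection = "aic_backward")
  expect_lt(sd(ps$scores), 0.02)
  expect_equal(mean(ps$scores), mean(cohort$treated), tolerance = 1e-6)
  # backward elimination strips most of the 6 null candidates
  expect_lte(length(ps$terms), 3)
})

test_that("propensity coefficients are recovered on a large cohort", {
  cfg <- registry_sim_config(n = 50000, seed = 62)
  cohort <- simulate_registry(cfg)
  ps <- fit_propensity(cohort, selection = "none")
  fit <- ps$model
  est <- coef(summary(fit))
  # generator codes age centred, T4/right/male as indicators; the glm uses
  # the raw columns, so slopes are directly comparable
  truth <- cfg$assignment_coefficients
  map <- c(age_years = "age", pt_stageT4 = "t4", nodes_lt10 = "nodes_lt10",
           diff_poor = "diff_poor", siteright = "right", sexM = "male")
  for (term in names(map)) {
    expect_lt(abs(est[term, "Estimate"] - truth[map[term]]),
              2 * est[term, "Std. Error"] + 0.02)
  }
  # confounded-by-indication cohort still shows score overlap between groups
  rng_t <- range(ps$scores[cohort$treated == 1])
  rng_c <- range(ps$scores[cohort$treated == 0])
  expect_lt(max(rng_t[1], rng_c[1]), min(rng_t[2], rng_c[2]))
})

test_that("perfect separation is reported as an error", {
  cohort <- simulate_registry(registry_sim_config(n = 300, seed = 63))
  cohort$flag <- cohort$treated  # deterministic predictor
  expect_error(fit_propensity(cohort, candidates = c("age_years", "flag"),
                              selection = "none"),
               "separation")
})

test_that("greedy matching follows the stated hand case and the oracle", {
  # treated PS {0.30, 0.20}, control PS {0.29, 0.28, 0.05}, caliper 0.05:
  # 0.30 pairs with 0.29; 0.20 finds nothing within the caliper
  cohort <- tibble::tibble(
    patient_id = letters[1:5], treated = c(1, 1, 0, 0, 0),
    time_months = 10, event = 1
  )
  model <- structure(
    list(treatment = "treated", scores = c(0.30, 0.20, 0.29, 0.28, 0.05),
         logit_scores = qlogis(c(0.30, 0.20, 0.29, 0.28, 0.05)),
         sd_logit = 1),
    class = "propensity_model")
  m <- match_pairs(cohort, model, caliper = 0.05)
  expect_equal(m$info$n_pairs, 1L)
  expect_equal(m$info$n_treated_dropped, 1L)
  expect_equal(sort(m$data$patient_id), c("a", "c"))

  # random cases against the plain-loop greedy oracle
  set.seed(64)
  for (rep in 1:20) {
    n_t <- sample(3:10, 1); n_c <- sample(5:20, 1)
    ps <- runif(n_t + n_c)
    trt <- rep(c(1, 0), c(n_t, n_c))
    co <- tibble::tibble(patient_id = as.character(seq_along(ps)),
                         treated = trt, time_months = 5, event = 1)
    mod <- structure(list(treatment = "treated", scores = ps,
                          logit_scores = qlogis(ps), sd_logit = sd(qlogis(ps))),
                     class = "propensity_model")
    cal <- runif(1, 0.01, 0.2)
    got <- match_pairs(co, mod, caliper = cal)
    want <- oracle_greedy_match(ps[trt == 1], ps[trt == 0], cal)
    expect_equal(got$info$n_pairs, if (is.null(want)) 0L else nrow(want))
    if (!is.null(want)) {
      ctl_rows <- which(trt == 0)[want[, "control"]]
      expect_setequal(got$info$pairs$control_row, ctl_rows)
    }
  }
})

test_that("matched samples satisfy the caliper and pair-disjointness", {
  cohort <- simulate_registry(registry_sim_config(n = 6000, seed = 65))
  ps <- fit_propensity(cohort, selection = "none")
  for (cal in c("exact", "sd0.2")) {
    m <- match_pairs(cohort, ps, caliper = cal)
    pairs <- m$info$pairs
    expect_gt(nrow(pairs), 0)
    ids <- c(pairs$treated_row, pairs$control_row)
    expect_equal(anyDuplicated(ids), 0)
    expect_true(all(pairs$distance <= m$info$caliper + 1e-12))
    expect_lte(nrow(m$data), 2 * sum(cohort$treated))
  }
  # identical scores: every treated patient is matched under both calipers
  const <- structure(list(treatment = "treated",
                          scores = rep(0.3, nrow(cohort)),
                          logit_scores = rep(qlogis(0.3), nrow(cohort)),
                          sd_logit = 0),
                     class = "propensity_model")
  for (cal in c("exact", "sd0.2")) {
    m <- match_pairs(cohort, const, caliper = cal)
    expect_equal(m$info$n_pairs, sum(cohort$treated))
  }
  # matching balances the confounders
  m <- match_pairs(cohort, ps, caliper = "sd0.2")
  bal <- smd_table(m$data, c("age_years", "pt_stage", "nodes_lt10", "site",
                             "diff_poor"))
  expect_true(all(abs(bal$smd) < 0.25))
})

test_that("stabilized IPW weights have the stated properties", {
  cohort <- simulate_registry(registry_sim_config(n = 20000, seed = 66))
  ps <- fit_propensity(cohort, selection = "none")
  w <- ipw_weights(cohort, ps)
  expect_true(all(w$data$weight > 0 & is.finite(w$data$weight)))
  expect_equal(sum(w$data$weight), nrow(cohort), tolerance = 0.05)
  expect_equal(mean(w$data$weight), 1, tolerance = 0.05)
  # invariant to relabeling of patients
  perm <- sample(nrow(cohort))
  ps_perm <- structure(list(treatment = "treated", scores = ps$scores[perm],
                            logit_scores = ps$logit_scores[perm],
                            sd_logit = ps$sd_logit),
                       class = "propensity_model")
  w_perm <- ipw_weights(cohort[perm, ], ps_perm)
  expect_equal(w_perm$data$weight, w$data$weight[perm])
  # constant score: every stabilized weight is exactly 1
  const <- structure(list(treatment = "treated",
                          scores = rep(mean(cohort$treated), nrow(cohort)),
                          logit_scores = rep(0, nrow(cohort)), sd_logit = 0),
                     class = "propensity_model")
  expect_equal(ipw_weights(cohort, const, truncate = NULL)$data$weight,
               rep(1, nrow(cohort)))
  # weighting balances the confounders on a correctly specified model
  bal <- smd_table(w$data, c("age_years", "pt_stage", "nodes_lt10", "site",
                             "diff_poor"), weights = w$data$weight)
  expect_true(all(abs(bal$smd) < 0.1))
})

test_that("stratification partitions the cohort into quantile subclasses", {
  cohort <- tibble::tibble(patient_id = as.character(1:1000),
                           treated = rep(0:1, 500),
                           time_months = 10, event = 1)
  model <- structure(list(treatment = "treated",
                          scores = seq(0.001, 0.999, length.out = 1000),
                          logit_scores = qlogis(seq(0.001, 0.999,
                                                    length.out = 1000)),
                          sd_logit = 1),
                     class = "propensity_model")
  st <- stratify(cohort, model, k = 5)
  expect_equal(unname(table(st$data$stratum)), rep(200L, 5),
               ignore_attr = TRUE)
  # strata are a partition
  expect_equal(sum(table(st$data$stratum)), nrow(cohort))
  expect_false(anyNA(st$data$stratum))
  # within-stratum score range is below the overall range
  rngs <- tapply(st$data$ps, st$data$stratum, function(x) diff(range(x)))
  expect_true(all(rngs < diff(range(model$scores))))
  # constant scores cannot be cut into distinct quantiles
  const <- structure(list(treatment = "treated",
                          scores = rep(0.5, 1000),
                          logit_scores = rep(0, 1000), sd_logit = 0),
                     class = "propensity_model")
  expect_error(stratify(cohort, const), "distinct")
})

test_that("adjustment variants agree with the naive fit when nothing confounds", {
  cfg <- registry_sim_config(
    n = 20000, seed = 67,
    assignment_coefficients = c(age = 0, t4 = 0, nodes_lt10 = 0,
                                diff_poor = 0, right = 0, male = 0),
    target_treated_fraction = 0.25, true_treatment_log_hr = 0
  )
  cohort <- simulate_registry(cfg)
  ps <- fit_propensity(cohort, selection = "none")
  naive <- estimate_effect(cohort)
  fits <- list(
    matched = estimate_effect(match_pairs(cohort, ps, "sd0.2"),
                              covariates = NULL),
    weighted = estimate_effect(ipw_weights(cohort, ps), covariates = NULL),
    stratified = estimate_effect(stratify(cohort, ps), covariates = NULL)
  )
  for (f in fits) {
    expect_lt(abs(f$log_hr - naive$log_hr), 0.08)
    expect_lt(abs(f$log_hr), 2.5 * f$se + 0.03)
  }
})

test_that("stratified pooling stays inside the per-stratum range", {
  cohort <- simulate_registry(registry_sim_config(n = 8000, seed = 68))
  ps <- fit_propensity(cohort, selection = "none")
  st <- stratify(cohort, ps)
  fit <- suppressWarnings(estimate_effect(st))
  expect_s3_class(fit, "pooled_strata_fit")
  expect_gte(fit$log_hr, min(fit$strata$log_hr))
  expect_lte(fit$log_hr, max(fit$strata$log_hr))
})
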
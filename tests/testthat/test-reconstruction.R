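test_that("preprocess_curve normalizes digitized coordinates", {
  ok <- data.frame(time_months = c(0, 12, 24), survival = c(1, 0.9, 0.8))
  expect_equal(as.data.frame(preprocess_curve(ok)), ok)

  wobble <- data.frame(time_months = c(0, 6, 12, 24),
                       survival = c(1, 0.92, 0.93, 0.85))
  out <- preprocess_curve(wobble)
  expect_equal(out$survival[out$time_months == 12], 0.92)

  expect_error(preprocess_curve(data.frame(time_months = c(3, 3),
                                           survival = c(1, 0.9))),
               "distinct")
  # duplicate times collapse to the lowest survival
  dup <- preprocess_curve(data.frame(time_months = c(0, 12, 12),
                                     survival = c(1, 0.9, 0.85)))
  expect_equal(dup$survival, c(1, 0.85))
})

test_that("preprocessing equals the brute-force running minimum", {
  set.seed(11)
  for (rep in 1:20) {
    t <- c(0, sort(runif(15, 1, 70)))
    s_true <- c(1, cumprod(runif(15, 0.9, 1)))
    s_noisy <- c(1, pmin(pmax(s_true[-1] + runif(15, -0.01, 0.01), 0), 1))
    out <- preprocess_curve(data.frame(time_months = t, survival = s_noisy))
    expect_equal(out$survival, oracle_running_min(s_noisy))
  }
})

test_that("interval splits match the stated hand cases", {
  curve <- data.frame(time_months = c(0, 6, 12), survival = c(1, 0.95, 0.90))
  # 100 -> 90 with S 1.00 -> 0.90: all drop is events
  counts <- estimate_interval_counts(
    curve, data.frame(time_months = c(0, 12), n_at_risk = c(100, 90)))
  expect_equal(counts$d[1], 10L)
  expect_equal(counts$c[1], 0L)
  # 100 -> 95 with S constant: pure censoring
  flat <- data.frame(time_months = c(0, 12), survival = c(1, 1))
  counts <- estimate_interval_counts(
    flat, data.frame(time_months = c(0, 12), n_at_risk = c(100, 95)))
  expect_equal(counts$d[1], 0L)
  expect_equal(counts$c[1], 5L)
})

test_that("interval splits equal the exhaustive integer-search oracle", {
  set.seed(22)
  for (rep in 1:200) {
    n <- sample(2:200, 1)
    drop <- sample(0:n, 1)
    target <- runif(1, 0.3, 1)
    got <- kmpool:::split_interval_drop(n, drop, target)
    want <- oracle_split(n, drop, target)
    expect_equal(got$d, unname(want["d"]))
    expect_equal(got$c, unname(want["c"]))
  }
})

test_that("events are apportioned by largest remainder and censorings evenly", {
  # d = 5 over steps with drops 0.06 and 0.04 -> 3 and 2 events
  expect_equal(kmpool:::largest_remainder(5, c(0.06, 0.04)), c(3L, 2L))
  expect_equal(kmpool:::largest_remainder(3, 0.05), 3L)

  # flat curve, risk 10 -> 10 -> 8: two censorings on [12, 24) sit at 16, 20
  flat <- data.frame(time_months = c(0, 24), survival = c(1, 1))
  risk <- data.frame(time_months = c(0, 12, 24), n_at_risk = c(10, 10, 8))
  counts <- estimate_interval_counts(flat, risk)
  expect_equal(counts$c[2], 2L)
  ipd <- expand_to_ipd(counts, arm = "a", trial_id = "t")
  cens <- ipd$time_months[ipd$event == 0 & ipd$time_months > 12 &
                            ipd$time_months < 24]
  expect_equal(sort(cens), c(16, 20))

  # d = 3 over one digitized step at month 10 -> three event records at 10
  stepc <- data.frame(time_months = c(0, 10), survival = c(1, 0.7))
  counts2 <- estimate_interval_counts(
    stepc, data.frame(time_months = c(0, 12), n_at_risk = c(10, 7)))
  expect_equal(counts2$d[1], 3L)
  ipd2 <- expand_to_ipd(counts2, arm = "a", trial_id = "t")
  expect_equal(sum(ipd2$time_months == 10 & ipd2$event == 1), 3L)
})

test_that("reconstruction conserves counts and returns a valid step curve", {
  set.seed(33)
  cfg <- trial_sim_config(n_per_arm = 300, n_trials = 1, censor_rate = 0.004,
                          seed = 33)
  ipd <- simulate_trial_ipd(cfg)
  d <- ipd[ipd$arm == "control", ]
  agg <- aggregate_trial(d, risk_times = seq(0, 72, 12), noise_sd = 0.004)
  rec <- reconstruct_arm(agg$curves[c("time_months", "survival")],
                         agg$risk[c("time_months", "n_at_risk")])
  expect_equal(nrow(rec$ipd), agg$risk$n_at_risk[1])
  expect_true(all(rec$ipd$time_months > 0))
  km <- km_estimate(rec$ipd)$table
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
})

test_that("zero-noise round trip is lossless at risk-table times", {
  cfg <- trial_sim_config(n_per_arm = 250, n_trials = 1, censor_rate = 0,
                          seed = 44)
  ipd <- simulate_trial_ipd(cfg)
  for (a in unique(ipd$arm)) {
    d <- ipd[ipd$arm == a, ]
    agg <- aggregate_trial(d, risk_times = seq(0, 72, 12))
    rec <- reconstruct_arm(agg$curves[c("time_months", "survival")],
                           agg$risk[c("time_months", "n_at_risk")])
    expect_equal(rec$fidelity$max_km_deviation, 0)
    expect_equal(rec$fidelity$max_at_risk_difference, 0)
  }
})

test_that("an inconsistent risk table is clipped with a warning", {
  curve <- data.frame(time_months = c(0, 6, 12), survival = c(1, 0.9, 0.8))
  risk <- data.frame(time_months = c(0, 6, 12), n_at_risk = c(50, 45, 48))
  expect_warning(counts <- estimate_interval_counts(curve, risk), "clipped")
  expect_equal(counts$d[2], 0L)
  expect_equal(counts$c[2], 0L)
  expect_true(counts$clipped[2])
})

test_that("noisy reconstruction stays close to the true curve", {
  set.seed(55)
  ok <- replicate(40, {
    cfg <- trial_sim_config(n_per_arm = 500, n_trials = 1, censor_rate = 0.003,
                            seed = sample.int(1e6, 1))
    ipd <- simulate_trial_ipd(cfg)
    d <- ipd[ipd$arm == "control", ]
    agg <- aggregate_trial(d, risk_times = seq(0, 72, 12), noise_sd = 0.005)
    rec <- reconstruct_arm(agg$curves[c("time_months", "survival")],
                           agg$risk[c("time_months", "n_at_risk")])
    # deviation measured against the true product-limit curve of the source
    fit <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = d)
    s_true <- summary(fit, times = seq(0, 72, 12), extend = TRUE)$surv
    max(abs(rec$fidelity$table$survival_reconstructed - s_true)) <= 0.02
  })
  expect_gte(mean(ok), 0.95)
})
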
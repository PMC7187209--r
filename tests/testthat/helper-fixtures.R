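# Small in-code fixtures shared across test files.

# two-arm exponential trial data without trial heterogeneity
make_two_arm <- function(n_per_arm, log_hr, rate = 0.01, censor = 0.005,
                         admin = 72) {
  trt <- rep(0:1, each = n_per_arm)
  t_event <- rexp(2 * n_per_arm, rate * exp(log_hr * trt))
  t_cens <- pmin(rexp(2 * n_per_arm, censor), admin)
  data.frame(
    trial_id = "t1",
    arm = ifelse(trt == 1, "mono", "control"),
    patient_id = as.character(seq_len(2 * n_per_arm)),
    treated = trt,
    time_months = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens)
  )
}

# a small survival fixture with distinct times for oracle comparisons
make_cox_fixture <- function(n = 12, seed = 42) {
  withr::local_seed(seed, .local_envir = parent.frame())
  x <- rep(0:1, length.out = n)
  data.frame(
    time_months = sample(seq_len(n) * 1.5),  # distinct, shuffled
    event = rbinom(n, 1, 0.8),
    treated = x
  )
}
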
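# Independent brute-force oracles the implementation is checked against.
# These are written from the definitions, not by calling the package or
# survival.

# Cox partial log-likelihood for distinct event times (no ties), one binary
# covariate; written out term by term from the definition.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_score <- function(beta, time, event, x) {
  s <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    w <- exp(beta * x[risk])
    s <- s + x[i] - sum(w * x[risk]) / sum(w)
  }
  s
}

# Newton maximization of the explicit partial likelihood
oracle_cox_mle <- function(time, event, x, tol = 1e-12, max_iter = 200) {
  beta <- 0
  for (it in seq_len(max_iter)) {
    s <- oracle_cox_score(beta, time, event, x)
    h <- (oracle_cox_score(beta + 1e-6, time, event, x) - s) / 1e-6
    step <- s / abs(h)
    # step-halving on likelihood decrease
    ll0 <- oracle_cox_loglik(beta, time, event, x)
    while (oracle_cox_loglik(beta + step, time, event, x) < ll0 &&
           abs(step) > tol) {
      step <- step / 2
    }
    beta <- beta + step
    if (abs(s) < tol) break
  }
  beta
}

# elementwise running minimum by a brute-force loop
oracle_running_min <- function(x) {
  out <- x
  for (i in seq_along(x)[-1]) out[i] <- min(out[i - 1], x[i])
  out
}

# exhaustive integer search for the event/censoring split of one interval:
# all (d, c) with d + c = drop, censoring approximated by removing c/2 from
# the risk set before the events
oracle_split <- function(n_start, drop, target) {
  best <- NULL
  best_err <- Inf
  for (d in 0:drop) {
    c <- drop - d
    denom <- n_start - c / 2
    if (denom <= 0) next
    implied <- (denom - d) / denom
    err <- abs(implied - target)
    if (err < best_err - 1e-15) {
      best_err <- err
      best <- c(d = d, c = c)
    }
  }
  best
}

# plain-loop greedy 1:1 nearest-neighbour matching, treated in descending
# score order, without replacement
oracle_greedy_match <- function(ps_treated, ps_control, caliper) {
  ord <- order(ps_treated, decreasing = TRUE)
  used <- rep(FALSE, length(ps_control))
  pairs <- NULL
  for (i in ord) {
    best_j <- NA
    best_d <- Inf
    for (j in seq_along(ps_control)) {
      if (used[j]) next
      d <- abs(ps_control[j] - ps_treated[i])
      if (d < best_d) {
        best_d <- d
        best_j <- j
      }
    }
    if (!is.na(best_j) && best_d <= caliper) {
      used[best_j] <- TRUE
      pairs <- rbind(pairs, c(treated = i, control = best_j))
    }
  }
  pairs
}

# hand product-limit estimator (no package calls)
oracle_km <- function(time, event, at) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(at))
  for (k in seq_along(at)) {
    s <- 1
    for (t in ut[ut <= at[k]]) {
      n_risk <- sum(time >= t)
      d <- sum(time == t & event == 1)
      s <- s * (1 - d / n_risk)
    }
    out[k] <- s
  }
  out
}
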
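#' Fit a propensity-score model for treatment assignment
#'
#' Logistic regression of treatment on the candidate confounders, with
#' optional backward elimination by AIC starting from the full candidate set
#' (main effects plus, optionally, all pairwise covariate-by-covariate
#' interactions). The fitted probabilities are the propensity scores; their
#' logit-scale standard deviation is recorded because the wide caliper rule
#' is defined in those units.
#'
#' @param cohort Registry-style cohort data frame.
#' @param candidates Covariate column names eligible for the model.
#' @param treatment Name of the 0/1 treatment column.
#' @param selection `"aic_backward"` (default) or `"none"` (keep the full
#'   main-effects model).
#' @param interactions Include pairwise covariate interactions in the
#'   candidate set before elimination?
#' @return A `propensity_model`: the glm, selected terms, per-patient scores
#'   and logit scores, and `sd_logit`.
#' @export
fit_propensity <- function(cohort,
                           candidates = c("age_years", "sex", "pt_stage",
                                          "nodes_lt10", "site", "diff_poor"),
                           treatment = "treated",
                           selection = c("aic_backward", "none"),
                           interactions = FALSE) {
  selection <- match.arg(selection)
  trt <- cohort[[treatment]]
  if (length(unique(trt)) < 2) abort("both treated and untreated required.")
  rhs <- if (interactions && length(candidates) > 1) {
    paste0("(", paste(candidates, collapse = " + "), ")^2")
  } else {
    paste(candidates, collapse = " + ")
  }
  f <- as.formula(paste(treatment, "~", rhs))
  # separation surfaces as glm convergence chatter; we diagnose it ourselves
  fit <- withCallingHandlers(
    glm(f, data = cohort, family = binomial()),
    warning = function(w) {
      if (grepl("converge|fitted probabilities", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  coefs <- coef(fit)[-1]
  if (any(!is.finite(coefs)) || any(abs(coefs) > 15, na.rm = TRUE)) {
    bad <- names(coefs)[which.max(abs(coefs))]
    abort(paste0("perfect separation on `", bad, "`: propensity model ",
                 "coefficients diverge."))
  }
  if (selection == "aic_backward") {
    fit <- step(fit, direction = "backward", trace = 0,
                scope = list(lower = ~1))
  }
  scores <- unname(fitted(fit))
  structure(
    list(
      model = fit,
      terms = attr(fit$terms, "term.labels"),
      treatment = treatment,
      scores = scores,
      logit_scores = qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12)),
      sd_logit = sd(qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12)))
    ),
    class = "propensity_model"
  )
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("<propensity_model> terms:",
      if (length(x$terms)) paste(x$terms, collapse = ", ") else "(intercept only)",
      "\n")
  cat(sprintf("  scores: %.3f - %.3f; SD(logit) = %.3f\n",
              min(x$scores), max(x$scores), x$sd_logit))
  invisible(x)
}

new_adjusted_sample <- function(variant, data, info) {
  structure(list(variant = variant, data = tibble::as_tibble(data),
                 info = info),
            class = "adjusted_sample")
}

#' @export
print.adjusted_sample <- function(x, ...) {
  cat(sprintf("<adjusted_sample> variant = %s, %d records\n",
              x$variant, nrow(x$data)))
  invisible(x)
}

#' Greedy 1:1 propensity-score matching without replacement
#'
#' Treated patients are processed in descending propensity-score order; each
#' is matched to the nearest not-yet-used control within the caliper, and is
#' dropped (and counted) if none qualifies. Two named caliper rules mirror
#' the two matched samples of the emulated analysis: `"exact"` requires
#' propensity-score equality (tolerance 1e-10) — attainable because registry
#' covariate patterns repeat — and `"sd0.2"` allows 0.2 standard deviations
#' of the logit propensity score, with distance measured on the logit scale.
#' A numeric caliper is interpreted as a maximum distance on the probability
#' scale.
#'
#' @param cohort Cohort data frame (same rows the model was fitted on).
#' @param model A [fit_propensity()] result.
#' @param caliper `"exact"`, `"sd0.2"`, or a positive number.
#' @return An `adjusted_sample` (variant `"matched"`): the matched rows with
#'   `pair_id` and `ps`, plus matching provenance in `$info` (`caliper`,
#'   `n_pairs`, `n_treated_dropped`, the pair table).
#' @export
match_pairs <- function(cohort, model, caliper = "sd0.2") {
  stopifnot(inherits(model, "propensity_model"))
  if (is.character(caliper)) caliper <- match.arg(caliper, c("exact", "sd0.2"))
  if (is.numeric(caliper) && caliper < 0) abort("`caliper` must be >= 0.")
  use_logit <- identical(caliper, "sd0.2")
  x <- if (use_logit) model$logit_scores else model$scores
  cal <- if (identical(caliper, "exact")) {
    1e-10
  } else if (identical(caliper, "sd0.2")) {
    0.2 * model$sd_logit
  } else {
    caliper
  }
  trt_idx <- which(cohort[[model$treatment]] == 1)
  ctl_idx <- which(cohort[[model$treatment]] == 0)
  trt_idx <- trt_idx[order(model$scores[trt_idx], decreasing = TRUE)]
  available <- rep(TRUE, length(ctl_idx))
  pairs <- vector("list", length(trt_idx))
  dropped <- 0L
  for (k in seq_along(trt_idx)) {
    i <- trt_idx[k]
    dist <- abs(x[ctl_idx] - x[i])
    dist[!available] <- Inf
    j <- which.min(dist)
    if (is.finite(dist[j]) && dist[j] <= cal) {
      available[j] <- FALSE
      pairs[[k]] <- tibble::tibble(
        pair_id = NA_integer_, treated_row = i, control_row = ctl_idx[j],
        distance = dist[j])
    } else {
      dropped <- dropped + 1L
    }
  }
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0) {
    warn("no pairs satisfy the caliper; matched sample is empty.")
    return(new_adjusted_sample("matched", cohort[0, ],
                               list(caliper = cal, caliper_rule = caliper,
                                    n_pairs = 0L, n_treated_dropped = dropped,
                                    pairs = pairs)))
  }
  pairs$pair_id <- seq_len(nrow(pairs))
  rows <- c(rbind(pairs$treated_row, pairs$control_row))
  data <- cohort[rows, ]
  data$pair_id <- rep(pairs$pair_id, each = 2)
  data$ps <- model$scores[rows]
  new_adjusted_sample(
    "matched", data,
    list(caliper = cal, caliper_rule = caliper,
         n_pairs = nrow(pairs), n_treated_dropped = dropped, pairs = pairs)
  )
}

#' Inverse-probability-of-treatment weights
#'
#' ATE weights from the propensity score: treated patients receive
#' `1 / e(x)`, untreated `1 / (1 - e(x))`, stabilized by the marginal
#' treatment probabilities so that the weights average about 1. Scores are
#' optionally truncated before weighting to limit the influence of extreme
#' propensities.
#'
#' @inheritParams match_pairs
#' @param estimand Currently `"ATE"`.
#' @param stabilized Multiply by the marginal treated/untreated fractions?
#' @param truncate Length-2 bounds at which scores are truncated before
#'   weighting, or `NULL` for none.
#' @return An `adjusted_sample` (variant `"weighted"`): the cohort with a
#'   `weight` and `ps` column; `$info` records the estimand and truncation.
#' @export
ipw_weights <- function(cohort, model, estimand = "ATE", stabilized = TRUE,
                        truncate = c(0.01, 0.99)) {
  stopifnot(inherits(model, "propensity_model"))
  estimand <- match.arg(estimand, "ATE")
  e <- model$scores
  if (any(e <= 0 | e >= 1)) {
    abort("propensity scores must lie strictly inside (0,1) before weighting.")
  }
  if (!is.null(truncate)) e <- pmin(pmax(e, truncate[1]), truncate[2])
  trt <- as.numeric(cohort[[model$treatment]])
  p_t <- mean(trt)
  w <- ifelse(trt == 1, 1 / e, 1 / (1 - e))
  if (stabilized) w <- w * ifelse(trt == 1, p_t, 1 - p_t)
  data <- cohort
  data$weight <- w
  data$ps <- e
  new_adjusted_sample(
    "weighted", data,
    list(estimand = estimand, stabilized = stabilized, truncate = truncate)
  )
}

#' Propensity-score stratification into quantile subclasses
#'
#' Partitions the cohort into `k` mutually exclusive strata at the quantiles
#' of the propensity score. Strata without treated patients or without events
#' are flagged here and excluded (with a warning) when effects are pooled.
#'
#' @inheritParams match_pairs
#' @param k Number of strata (default 5, i.e. quintiles).
#' @return An `adjusted_sample` (variant `"stratified"`): the cohort with a
#'   `stratum` factor and `ps`; `$info` holds per-stratum counts.
#' @export
stratify <- function(cohort, model, k = 5) {
  stopifnot(inherits(model, "propensity_model"), k >= 2)
  e <- model$scores
  if (length(unique(e)) < k) {
    abort("fewer distinct propensity scores than strata: no distinct quantiles.")
  }
  breaks <- quantile(e, probs = seq(0, 1, length.out = k + 1))
  if (anyDuplicated(breaks)) {
    abort("tied propensity-score quantiles: strata would not be distinct.")
  }
  data <- cohort
  data$stratum <- cut(e, breaks = breaks, include.lowest = TRUE,
                      labels = paste0("Q", seq_len(k)))
  data$ps <- e
  trt <- data[[model$treatment]]
  counts <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(stratum = data$stratum, treated = trt,
                                   event = data$event),
                    .data$stratum),
    n = dplyr::n(), n_treated = sum(.data$treated),
    n_events = sum(.data$event), .groups = "drop"
  )
  new_adjusted_sample("stratified", data, list(k = k, counts = counts))
}

#' Estimate the treatment effect, naively or on an adjusted sample
#'
#' The naive estimate is an unadjusted Cox model on the raw cohort. On a
#' matched sample the multivariate Cox model uses a pair-clustered robust
#' variance; on a weighted sample a weighted multivariate Cox model with a
#' robust sandwich variance; on a stratified sample per-stratum multivariate
#' Cox fits pooled by fixed-effect inverse-variance averaging of the log
#' hazard ratios (strata with no treated patients, no events, or no
#' treatment contrast are excluded with a warning).
#'
#' @param x A cohort data frame (naive estimate) or an `adjusted_sample`.
#' @param covariates Covariates of the multivariate model; ignored for the
#'   naive fit.
#' @param treatment,time,event Column names.
#' @return A `cox_fit` (for stratified samples, a `pooled_strata_fit` whose
#'   `strata` field holds the per-stratum fits).
#' @export
estimate_effect <- function(x,
                            covariates = c("age_years", "pt_stage",
                                           "nodes_lt10", "site", "diff_poor"),
                            treatment = "treated",
                            time = "time_months", event = "event") {
  if (!inherits(x, "adjusted_sample")) {
    return(cox_fit(x, treatment, covariates = NULL, time = time, event = event))
  }
  data <- x$data
  if (nrow(data) == 0 || sum(data[[event]]) == 0) {
    abort("adjusted sample has no usable events.")
  }
  switch(
    x$variant,
    matched = cox_fit(data, treatment, covariates = covariates,
                      time = time, event = event, cluster = "pair_id"),
    weighted = cox_fit(data, treatment, covariates = covariates,
                       time = time, event = event, weights = data$weight),
    stratified = pooled_strata_fit(data, covariates, treatment, time, event),
    abort(paste0("unknown adjusted-sample variant `", x$variant, "`."))
  )
}

pooled_strata_fit <- function(data, covariates, treatment, time, event) {
  fits <- list()
  excluded <- character(0)
  for (s in levels(data$stratum)) {
    d <- data[data$stratum == s, ]
    usable <- nrow(d) > 0 && sum(d[[event]]) > 0 &&
      length(unique(d[[treatment]])) == 2 && sum(d[[treatment]]) > 0
    if (!usable) {
      excluded <- c(excluded, s)
      next
    }
    fits[[s]] <- tryCatch(
      cox_fit(d, treatment, covariates = covariates,
              time = time, event = event),
      error = function(e) NULL
    )
    if (is.null(fits[[s]])) excluded <- c(excluded, s)
  }
  fits <- Filter(Negate(is.null), fits)
  if (length(excluded)) {
    warn(paste0("strata excluded from pooling (no treated/no events/",
                "unestimable): ", paste(excluded, collapse = ", ")))
  }
  if (length(fits) == 0) abort("all strata excluded: nothing to pool.")
  betas <- vapply(fits, function(f) f$log_hr, 0)
  ses <- vapply(fits, function(f) f$se, 0)
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- beta / se
  per_stratum <- tibble::tibble(
    stratum = names(fits), log_hr = betas, se = ses,
    n = vapply(fits, function(f) f$n, 0),
    events = vapply(fits, function(f) f$events, 0)
  )
  structure(
    list(term = treatment, log_hr = beta, se = se, hr = exp(beta),
         ci_lower = exp(beta - qnorm(0.975) * se),
         ci_upper = exp(beta + qnorm(0.975) * se),
         z = z, p_value = 2 * pnorm(-abs(z)),
         ties = "efron", n = sum(per_stratum$n),
         events = sum(per_stratum$events),
         strata = per_stratum, excluded_strata = excluded),
    class = c("pooled_strata_fit", "cox_fit")
  )
}
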
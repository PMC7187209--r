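#' Product-limit survival curve with Greenwood variance
#'
#' @param data Patient-level data frame.
#' @param time,event Column names of the follow-up time (months) and 0/1
#'   event flag.
#' @return An object of class `km_curve`: a list with `table` (tibble of
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`, `std_err` — the
#'   Greenwood standard error of S(t)), plus totals `n` and `events`.
#' @export
#' @examples
#' d <- data.frame(time_months = 1:4, event = c(1, 0, 1, 1))
#' km_estimate(d)$table
km_estimate <- function(data, time = "time_months", event = "event") {
  if (nrow(data) == 0) abort("`data` is empty.")
  f <- as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ 1"))
  fit <- survival::survfit(f, data = data)
  sm <- summary(fit, censored = TRUE)
  tab <- tibble::tibble(
    time = c(0, sm$time),
    n_risk = c(fit$n, sm$n.risk),
    n_event = c(0, sm$n.event),
    n_censor = c(0, sm$n.censor),
    survival = c(1, sm$surv),
    std_err = c(0, ifelse(is.finite(sm$std.err), sm$std.err, 0))
  )
  structure(list(table = tab, n = fit$n, events = sum(tab$n_event)),
            class = "km_curve")
}

#' Evaluate a `km_curve` at given times
#'
#' Step-function lookup of survival and its Greenwood standard error.
#'
#' @param curve A [km_estimate()] result.
#' @param times Numeric times (months).
#' @return A tibble `time`, `survival`, `std_err`.
#' @export
km_at <- function(curve, times) {
  stopifnot(inherits(curve, "km_curve"))
  idx <- findInterval(times, curve$table$time)
  idx[idx < 1] <- 1
  tibble::tibble(time = times,
                 survival = curve$table$survival[idx],
                 std_err = curve$table$std_err[idx])
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d\n", x$n, x$events))
  print(x$table, n = 6)
  invisible(x)
}

build_surv_formula <- function(time, event, treatment, covariates = NULL,
                               extra = NULL) {
  rhs <- paste(c(treatment, covariates, extra), collapse = " + ")
  as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ", rhs))
}

new_cox_fit <- function(fit, treatment, data, event, ties,
                        class = "cox_fit", extra = list()) {
  beta <- unname(coef(fit)[treatment])
  se <- sqrt(diag(fit$var))[match(treatment, names(coef(fit)))]
  se <- unname(se)
  z <- beta / se
  out <- c(
    list(
      term = treatment,
      log_hr = beta, se = se, hr = exp(beta),
      ci_lower = exp(beta - qnorm(0.975) * se),
      ci_upper = exp(beta + qnorm(0.975) * se),
      z = z, p_value = 2 * pnorm(-abs(z)),
      ties = ties, n = fit$n, events = sum(data[[event]]),
      fit = fit
    ),
    extra
  )
  structure(out, class = unique(c(class, "cox_fit")))
}

#' Cox proportional-hazards fit for a treatment effect
#'
#' Maximizes the Cox partial likelihood with Efron tie handling by default
#' (reconstructed data is tie-heavy because events sit on digitized step
#' times). The standard error comes from the observed information; the CI is
#' Wald on the log-hazard scale.
#'
#' @param data Patient-level data frame.
#' @param treatment Name of the 0/1 (or logical) treatment column.
#' @param covariates Optional further covariate column names.
#' @param time,event Column names of follow-up time and event flag.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param weights Optional per-record weights (a numeric vector); a robust
#'   sandwich variance is used automatically when supplied.
#' @param cluster Optional name of a cluster id column; enables a robust
#'   cluster variance (e.g. matched pairs).
#' @return A `cox_fit`: log hazard ratio, standard error, hazard ratio with
#'   95% Wald CI, Wald p-value, `n` and `events`, plus the underlying
#'   [survival::coxph()] fit.
#' @export
cox_fit <- function(data, treatment = "treated", covariates = NULL,
                    time = "time_months", event = "event",
                    ties = c("efron", "breslow"),
                    weights = NULL, cluster = NULL) {
  ties <- match.arg(ties)
  if (sum(data[[event]]) < 1) abort("need at least one event.")
  if (length(unique(data[[treatment]])) < 2) {
    abort("`treatment` does not vary.")
  }
  data <- as.data.frame(data)
  if (!is.null(weights)) data$.w <- weights
  f <- build_surv_formula(time, event, treatment, covariates)
  args <- list(formula = f, data = data, ties = ties,
               control = survival::coxph.control(eps = 1e-10, iter.max = 100))
  if (!is.null(weights)) {
    args$weights <- data$.w
    args$robust <- TRUE
  }
  if (!is.null(cluster)) {
    args$cluster <- data[[cluster]]
    args$robust <- TRUE
  }
  # a monotone likelihood surfaces as a convergence warning; we diagnose it
  # ourselves and abort with the offending term
  fit <- withCallingHandlers(
    do.call(survival::coxph, args),
    warning = function(w) {
      if (grepl("coefficient may be infinite", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 15)) {
    bad <- names(coef(fit))[which.max(abs(coef(fit)))]
    abort(paste0("monotone partial likelihood: coefficient for `", bad,
                 "` diverges (complete separation of risk sets)."))
  }
  new_cox_fit(fit, treatment, data, event, ties)
}

#' Multilevel Cox fit with a per-group log-normal frailty
#'
#' Adds a Normal(0, tau^2) random intercept on the log hazard for each group
#' (trial), estimated by penalized partial likelihood; the reported standard
#' error comes from the penalized information and the CI is Wald on the log
#' scale. With `theta = 0` the model reduces exactly to the plain Cox fit.
#' With a single group the function warns and falls back to the plain fit.
#'
#' @inheritParams cox_fit
#' @param group Name of the grouping (trial id) column.
#' @param theta Optional fixed value for the frailty variance tau^2; `NULL`
#'   (default) estimates it.
#' @return A `frailty_cox_fit` (also a `cox_fit`) with extra fields `tau2`
#'   (the estimated or fixed frailty variance) and `trial_effects` (per-group
#'   predicted random intercepts).
#' @export
multilevel_cox_fit <- function(data, treatment = "treated",
                               group = "trial_id",
                               time = "time_months", event = "event",
                               ties = c("efron", "breslow"), theta = NULL) {
  ties <- match.arg(ties)
  data <- as.data.frame(data)
  groups <- unique(data[[group]])
  if (length(groups) < 2) {
    warn(paste0("fewer than 2 groups: frailty variance not identifiable, ",
                "falling back to the plain Cox fit."))
    theta <- 0
  }
  if (!is.null(theta) && theta == 0) {
    plain <- cox_fit(data, treatment, time = time, event = event, ties = ties)
    return(new_cox_fit(
      plain$fit, treatment, data, event, ties,
      class = "frailty_cox_fit",
      extra = list(tau2 = 0,
                   trial_effects = setNames(rep(0, length(groups)),
                                            as.character(groups)))
    ))
  }
  if (sum(data[[event]]) < 1) abort("need at least one event.")
  frail <- if (is.null(theta)) {
    paste0("survival::frailty.gaussian(", group, ")")
  } else {
    paste0("survival::frailty.gaussian(", group, ", theta = ", theta, ")")
  }
  f <- build_surv_formula(time, event, treatment, extra = frail)
  fit <- survival::coxph(f, data = data, ties = ties,
                         control = survival::coxph.control(
                           eps = 1e-9, iter.max = 100, outer.max = 30))
  tau2 <- fit$history[[1]]$theta
  # with few groups the frailty coefficients are kept dense inside coef();
  # with many they are sparse and live in fit$frail
  ranef <- if (!is.null(fit$frail)) {
    setNames(fit$frail, as.character(sort(groups)))
  } else {
    b <- coef(fit)[grep("^gauss:", names(coef(fit)))]
    setNames(unname(b), sub("^gauss:", "", names(b)))
  }
  new_cox_fit(
    fit, treatment, data, event, ties, class = "frailty_cox_fit",
    extra = list(tau2 = tau2, trial_effects = ranef)
  )
}

#' Pool trial arms and fit the requested treatment-effect model
#'
#' Concatenates, for each listed trial, the two named arms, codes the
#' treatment indicator, preserves trial labels, and fits either a plain Cox
#' model or the multilevel (trial-frailty) model. This is the pooled-analysis
#' step of the trial track: pooling the reconstructed arms keeps each trial's
#' own randomized contrast.
#'
#' @param ipd Patient-level tibble (`trial_id`, `arm`, `time_months`,
#'   `event`).
#' @param spec Data frame with one row per trial: `trial_id`,
#'   `control_arm`, `treatment_arm`.
#' @param multilevel Fit the trial-frailty model?
#' @param ties Tie handling, see [cox_fit()].
#' @return A `cox_fit` / `frailty_cox_fit` with an extra `arm_summary`
#'   tibble (per-role `n` and `events`).
#' @export
pooled_comparison <- function(ipd, spec, multilevel = FALSE,
                              ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  spec <- as.data.frame(spec)
  stopifnot(all(c("trial_id", "control_arm", "treatment_arm") %in% names(spec)))
  if (any(spec$control_arm == spec$treatment_arm)) {
    abort("a trial lists identical comparator and treatment arms.")
  }
  pooled <- purrr::pmap_dfr(spec, function(trial_id, control_arm, treatment_arm) {
    d <- ipd[ipd$trial_id == trial_id & ipd$arm %in% c(control_arm, treatment_arm), ]
    for (a in c(control_arm, treatment_arm)) {
      if (!any(d$arm == a)) {
        abort(paste0("arm `", a, "` missing for trial `", trial_id, "`."))
      }
    }
    d$treated <- as.integer(d$arm == treatment_arm)
    d
  })
  arm_summary <- dplyr::summarise(
    dplyr::group_by(pooled, role = ifelse(.data$treated == 1, "treated", "control")),
    n = dplyr::n(), events = sum(.data$event), .groups = "drop"
  )
  fit <- if (multilevel) {
    multilevel_cox_fit(pooled, "treated", group = "trial_id", ties = ties)
  } else {
    cox_fit(pooled, "treated", ties = ties)
  }
  fit$arm_summary <- arm_summary
  fit$pooled_ipd <- tibble::as_tibble(pooled)
  fit
}

#' Weibull proportional-hazards fit for a treatment effect
#'
#' Maximum-likelihood parametric companion to [cox_fit()], in the
#' proportional-hazards parameterization (the treatment coefficient is a log
#' hazard ratio directly); with shape = 1 it reduces to the exponential
#' model.
#'
#' @inheritParams cox_fit
#' @return A `weibull_ph_fit` with `log_hr`, `se`, `hr`, 95% CI, Wald
#'   p-value, and the `shape` and `scale` of the baseline hazard.
#' @export
weibull_ph_fit <- function(data, treatment = "treated",
                           time = "time_months", event = "event") {
  if (sum(data[[event]]) < 1) abort("need at least one event.")
  if (length(unique(data[[treatment]])) < 2) abort("`treatment` does not vary.")
  data <- as.data.frame(data)
  f <- build_surv_formula(time, event, treatment)
  fit <- flexsurv::flexsurvreg(f, data = data, dist = "weibullPH")
  est <- fit$res[treatment, ]
  beta <- unname(est["est"])
  se <- unname(est["se"])
  z <- beta / se
  structure(
    list(term = treatment, log_hr = beta, se = se, hr = exp(beta),
         ci_lower = exp(beta - qnorm(0.975) * se),
         ci_upper = exp(beta + qnorm(0.975) * se),
         z = z, p_value = 2 * pnorm(-abs(z)),
         shape = unname(fit$res["shape", "est"]),
         scale = unname(fit$res["scale", "est"]),
         n = nrow(data), events = sum(data[[event]]), fit = fit),
    class = c("weibull_ph_fit", "cox_fit")
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<%s> %s: HR %.3f (95%% CI %.3f; %.3f), p = %.3g\n",
              class(x)[1], x$term, x$hr, x$ci_lower, x$ci_upper, x$p_value))
  cat(sprintf("  log HR %.4f (se %.4f); n = %d, events = %d\n",
              x$log_hr, x$se, x$n, x$events))
  if (!is.null(x$tau2)) cat(sprintf("  frailty variance tau^2 = %.4f\n", x$tau2))
  invisible(x)
}

#' @rdname cox_fit
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  tibble::tibble(
    term = x$term, estimate = x$log_hr, std.error = x$se,
    statistic = x$z, p.value = x$p_value,
    hr = x$hr, conf.low = x$ci_lower, conf.high = x$ci_upper
  )
}

#' @rdname cox_fit
#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, events = x$events,
    ties = x$ties %||% NA_character_,
    tau2 = x$tau2 %||% NA_real_
  )
}
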
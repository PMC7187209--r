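#' Clean digitized Kaplan-Meier coordinates
#'
#' Digitized curve readings carry manual reading error: survival values can
#' exceed 1, wobble upwards, or repeat a time. This normalizes raw
#' coordinates into a valid step function: values clipped to `[0,1]`,
#' duplicate times collapsed to their lowest survival, `(0, 1)` prepended when
#' absent, survival at time 0 fixed at 1, and monotonicity restored by a
#' running minimum.
#'
#' @param points Data frame with columns `time_months` and `survival`
#'   (a two-column matrix/data frame in that order is also accepted).
#' @return A tibble `time_months`, `survival` — a valid digitized curve.
#' @export
#' @examples
#' preprocess_curve(data.frame(time_months = c(0, 6, 12, 24),
#'                             survival = c(1, 0.92, 0.93, 0.85)))
preprocess_curve <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("time_months", "survival") %in% names(points))) {
    names(points)[1:2] <- c("time_months", "survival")
  }
  t <- points$time_months
  s <- points$survival
  if (any(!is.finite(t)) || any(t < 0)) abort("times must be finite and >= 0.")
  if (length(unique(t)) < 2) abort("need at least 2 distinct times.")
  s <- pmin(pmax(s, 0), 1)
  ord <- order(t, s)
  t <- t[ord]; s <- s[ord]
  keep <- !duplicated(t)            # sorted by (t, s): first kept is lowest s
  t <- t[keep]; s <- s[keep]
  if (t[1] != 0) {
    t <- c(0, t); s <- c(1, s)
  }
  s[1] <- 1
  tibble::tibble(time_months = t, survival = cummin(s))
}

validate_risk_table <- function(risk) {
  risk <- as.data.frame(risk)
  if (!all(c("time_months", "n_at_risk") %in% names(risk))) {
    names(risk)[1:2] <- c("time_months", "n_at_risk")
  }
  if (risk$time_months[1] != 0) abort("risk table must start at time 0.")
  if (is.unsorted(risk$time_months, strictly = TRUE)) {
    abort("risk-table times must be strictly increasing.")
  }
  if (any(risk$n_at_risk < 0)) abort("numbers at risk must be non-negative.")
  tibble::as_tibble(risk[c("time_months", "n_at_risk")])
}

# step-function (last observation carried forward) lookup of survival
curve_surv_at <- function(curve, times) {
  idx <- findInterval(times, curve$time_months)
  idx[idx < 1] <- 1
  curve$survival[idx]
}

#' Estimate per-interval event and censoring counts from published aggregates
#'
#' For each interval between consecutive risk-table times, splits the observed
#' decline in the number at risk into `d` events and `c` censorings such that
#' the conditional survival implied by the split — with censoring spread
#' uniformly through the interval, approximated by removing `c/2` from the
#' risk set before the events — comes as close as possible to the reported
#' ratio `S(T[j+1]) / S(T[j])`. The split is found by exhaustive search over
#' all non-negative integer pairs with `d + c` equal to the observed decline.
#' Patients remaining past the last risk-table time are allocated events from
#' residual curve drops, the rest being administratively censored at the
#' curve's end.
#'
#' @param curve A digitized curve (see [preprocess_curve()]).
#' @param risk A risk table (`time_months`, `n_at_risk`), starting at 0.
#' @return A tibble of class `interval_counts`: one row per interval with
#'   `t_start`, `t_end`, `n_start`, `n_end`, `d`, `c`, `target_ratio`,
#'   `implied_ratio`, `clipped`, `tail`. The input curve is attached as an
#'   attribute for downstream expansion.
#' @export
estimate_interval_counts <- function(curve, risk) {
  curve <- preprocess_curve(curve)
  risk <- validate_risk_table(risk)
  tt <- risk$time_months
  nn <- risk$n_at_risk
  s_at <- curve_surv_at(curve, tt)
  rows <- vector("list", length(tt))
  for (j in seq_len(length(tt) - 1)) {
    n_j <- nn[j]; n_next <- nn[j + 1]
    drop <- n_j - n_next
    clipped <- FALSE
    if (drop < 0) {
      warn(sprintf(
        "risk table rises from %d to %d at t=%g; counts clipped to 0",
        n_j, n_next, tt[j + 1]))
      drop <- 0
      clipped <- TRUE
    }
    target <- if (s_at[j] > 0) s_at[j + 1] / s_at[j] else 1
    split <- split_interval_drop(n_j, drop, target)
    rows[[j]] <- tibble::tibble(
      t_start = tt[j], t_end = tt[j + 1], n_start = n_j, n_end = n_j - drop,
      d = split$d, c = split$c, target_ratio = target,
      implied_ratio = split$implied, clipped = clipped, tail = FALSE
    )
  }
  # tail: everyone still at risk at the last reported time
  J <- length(tt)
  n_tail <- nn[J]
  t_end_curve <- max(curve$time_months)
  s_last <- s_at[J]
  s_end <- curve$survival[nrow(curve)]
  r_tail <- if (s_last > 0) s_end / s_last else 1
  d_tail <- min(max(round(n_tail * (1 - r_tail)), 0), n_tail)
  rows[[J]] <- tibble::tibble(
    t_start = tt[J], t_end = max(t_end_curve, tt[J]), n_start = n_tail,
    n_end = 0L, d = as.integer(d_tail), c = as.integer(n_tail - d_tail),
    target_ratio = r_tail,
    implied_ratio = if (n_tail > 0) (n_tail - d_tail) / n_tail else 1,
    clipped = FALSE, tail = TRUE
  )
  out <- dplyr::bind_rows(rows)
  attr(out, "curve") <- curve
  class(out) <- c("interval_counts", class(out))
  out
}

# exhaustive integer search: d + c = drop, censoring removes c/2 from the risk
# set before the events act
split_interval_drop <- function(n_start, drop, target) {
  if (drop == 0 || n_start == 0) {
    return(list(d = 0L, c = as.integer(drop), implied = 1))
  }
  d_cand <- 0:drop
  c_cand <- drop - d_cand
  denom <- n_start - c_cand / 2
  implied <- ifelse(denom > 0, (denom - d_cand) / denom, NA_real_)
  err <- abs(implied - target)
  err[is.na(err)] <- Inf
  best <- which.min(err)   # ties resolved toward the fewest events
  list(d = as.integer(d_cand[best]), c = as.integer(c_cand[best]),
       implied = implied[best])
}

#' Expand interval counts into pseudo individual-patient data
#'
#' Places each interval's events at the digitized step times inside the
#' interval, apportioned proportionally to the step drop sizes with
#' largest-remainder integer rounding, and its censorings at evenly spaced
#' times strictly inside the interval. Tail-interval censorings are
#' administrative and sit at the curve's end.
#'
#' @param counts An `interval_counts` object from [estimate_interval_counts()].
#' @param curve Digitized curve; defaults to the one attached to `counts`.
#' @param arm,trial_id Labels stamped onto every record.
#' @return An IPD tibble (`trial_id`, `arm`, `patient_id`, `time_months`,
#'   `event`) with exactly as many records as patients at risk at time 0.
#' @export
expand_to_ipd <- function(counts, curve = attr(counts, "curve"),
                          arm = "arm", trial_id = "trial") {
  stopifnot(inherits(counts, "interval_counts"))
  curve <- preprocess_curve(curve)
  recs <- purrr::pmap_dfr(
    counts[c("t_start", "t_end", "d", "c", "tail")],
    function(t_start, t_end, d, c, tail) {
      ev_times <- place_events(curve, t_start, t_end, d)
      cs_times <- if (c > 0) {
        if (tail) {
          rep(max(t_end, t_start), c)
        } else {
          t_start + (t_end - t_start) * seq_len(c) / (c + 1)
        }
      } else {
        numeric(0)
      }
      tibble::tibble(
        time_months = c(ev_times, cs_times),
        event = rep(c(1L, 0L), c(length(ev_times), length(cs_times)))
      )
    }
  )
  recs <- dplyr::arrange(recs, .data$time_months, dplyr::desc(.data$event))
  tibble::tibble(
    trial_id = trial_id, arm = arm,
    patient_id = sprintf("%s_%s_%04d", trial_id, arm, seq_len(nrow(recs))),
    time_months = recs$time_months, event = recs$event
  )
}

# events sit on the digitized step times in (t_start, t_end], split
# proportionally to drop sizes by largest remainder
place_events <- function(curve, t_start, t_end, d) {
  if (d == 0) return(numeric(0))
  drops <- diff(curve$survival) * -1
  times <- curve$time_months[-1]
  inside <- times > t_start & times <= t_end
  cand_t <- times[inside & drops > 0]
  cand_w <- drops[inside & drops > 0]
  if (length(cand_t) == 0) {
    cand_t <- times[inside]
    cand_w <- rep(1, length(cand_t))
  }
  if (length(cand_t) == 0) {
    cand_t <- (t_start + t_end) / 2
    cand_w <- 1
  }
  rep(cand_t, largest_remainder(d, cand_w))
}

# apportion `total` integer units proportionally to weights
largest_remainder <- function(total, weights) {
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Reconstruct one trial arm from its published aggregates
#'
#' Composes [preprocess_curve()], [estimate_interval_counts()] and
#' [expand_to_ipd()], and attaches a fidelity report comparing the
#' reconstruction's Kaplan-Meier curve and implied numbers at risk to the
#' inputs at every risk-table time.
#'
#' @inheritParams estimate_interval_counts
#' @param arm,trial_id Labels stamped onto the output records.
#' @return A list of class `km_reconstruction` with elements `ipd` (the
#'   reconstructed patient-level tibble) and `fidelity` (a list with
#'   `max_km_deviation`, `max_at_risk_difference`, a per-time `table`, and the
#'   total `n`, `events`, `censored`).
#' @export
reconstruct_arm <- function(curve, risk, arm = "arm", trial_id = "trial") {
  curve <- preprocess_curve(curve)
  risk <- validate_risk_table(risk)
  counts <- estimate_interval_counts(curve, risk)
  ipd <- expand_to_ipd(counts, curve, arm = arm, trial_id = trial_id)
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = ipd)
  s_recon <- summary(fit, times = risk$time_months, extend = TRUE)$surv
  s_input <- curve_surv_at(curve, risk$time_months)
  n_implied <- vapply(risk$time_months,
                      function(t) sum(ipd$time_months >= t), 0L)
  tab <- tibble::tibble(
    time_months = risk$time_months,
    survival_input = s_input, survival_reconstructed = s_recon,
    km_deviation = abs(s_recon - s_input),
    n_at_risk_reported = risk$n_at_risk, n_at_risk_implied = n_implied,
    at_risk_difference = n_implied - risk$n_at_risk
  )
  structure(
    list(
      ipd = ipd,
      counts = counts,
      fidelity = list(
        max_km_deviation = max(tab$km_deviation),
        max_at_risk_difference = max(abs(tab$at_risk_difference)),
        table = tab,
        n = nrow(ipd), events = sum(ipd$event),
        censored = sum(ipd$event == 0)
      )
    ),
    class = "km_reconstruction"
  )
}

#' @export
print.km_reconstruction <- function(x, ...) {
  cat(sprintf(
    "<km_reconstruction> %d patients (%d events, %d censored)\n",
    x$fidelity$n, x$fidelity$events, x$fidelity$censored))
  cat(sprintf("  max |KM deviation| at risk-table times: %.4g\n",
              x$fidelity$max_km_deviation))
  cat(sprintf("  max |at-risk difference|: %d\n",
              x$fidelity$max_at_risk_difference))
  invisible(x)
}
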
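#' Interaction test between two independent hazard-ratio estimates
#'
#' z-test on the difference of two log hazard ratios from independent data
#' sources, with variance equal to the sum of the squared standard errors —
#' the standard test for interaction between two estimates. The default
#' significance threshold is 0.10, a lenient level chosen to limit the type
#' II error of declaring two tracks concordant.
#'
#' @param fit1,fit2 `cox_fit`-like objects, or lists/named vectors carrying
#'   `log_hr` and `se`.
#' @param alpha Two-sided significance level.
#' @return An `interaction_result`: `diff_log_hr`, `se`, `z`, `p_value`,
#'   the ratio of hazard ratios with 95% CI, and `significant`.
#' @export
#' @examples
#' interaction_test(list(log_hr = -0.25, se = 0.10),
#'                  list(log_hr = 0, se = 0.20))
interaction_test <- function(fit1, fit2, alpha = 0.10) {
  b1 <- fit1[["log_hr"]]; s1 <- fit1[["se"]]
  b2 <- fit2[["log_hr"]]; s2 <- fit2[["se"]]
  if (!all(is.finite(c(b1, s1, b2, s2))) || s1 <= 0 || s2 <= 0) {
    abort("both fits must carry finite `log_hr` and positive `se`.")
  }
  d <- b1 - b2
  se <- sqrt(s1^2 + s2^2)
  z <- d / se
  p <- 2 * pnorm(-abs(z))
  structure(
    list(diff_log_hr = d, se = se, z = z, p_value = p,
         ratio_hr = exp(d),
         ratio_ci_lower = exp(d - qnorm(0.975) * se),
         ratio_ci_upper = exp(d + qnorm(0.975) * se),
         alpha = alpha, significant = p < alpha),
    class = "interaction_result"
  )
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf(
    "<interaction_result> ratio of HRs %.3f (95%% CI %.3f; %.3f)\n",
    x$ratio_hr, x$ratio_ci_lower, x$ratio_ci_upper))
  cat(sprintf("  z = %.3f, p = %.4f (%ssignificant at alpha = %.2f)\n",
              x$z, x$p_value, if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' @rdname interaction_test
#' @param x An `interaction_result`.
#' @param ... Unused.
#' @method tidy interaction_result
#' @export
tidy.interaction_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$diff_log_hr, std.error = x$se, statistic = x$z,
    p.value = x$p_value, ratio_hr = x$ratio_hr,
    conf.low = x$ratio_ci_lower, conf.high = x$ratio_ci_upper
  )
}

#' Homogeneity of 5-year disease-free survival across pooled arms
#'
#' Pairwise z-tests on the complementary-log-log transform of S(t) — a
#' variance-stabilizing, range-respecting scale for survival probabilities —
#' with delta-method variances from the Greenwood standard errors. Pairs in
#' which S(t) is exactly 0 or 1 are skipped with a warning, and the p-values
#' are reported unadjusted together with the number of comparisons made.
#'
#' @param curves Named list of [km_estimate()] curves (one per pooled arm).
#' @param t Evaluation time in months (default 60, i.e. 5-year DFS).
#' @param alpha Significance level for flagging.
#' @return A `homogeneity_result` with a `pairs` tibble (arms, survival
#'   estimates, `z`, `p_value`), `max_abs_z` and `n_comparisons`.
#' @export
homogeneity_test <- function(curves, t = 60, alpha = 0.05) {
  stopifnot(is.list(curves), length(curves) >= 2)
  if (is.null(names(curves))) names(curves) <- paste0("arm", seq_along(curves))
  ev <- purrr::map_dfr(names(curves), function(nm) {
    at <- km_at(curves[[nm]], t)
    tibble::tibble(arm = nm, survival = at$survival, std_err = at$std_err)
  })
  # delta method: var(log(-log S)) = var(S) / (S * log S)^2
  ev$g <- log(-log(pmin(pmax(ev$survival, .Machine$double.eps), 1)))
  ev$se_g <- ev$std_err / abs(ev$survival * log(ev$survival))
  idx <- utils::combn(seq_len(nrow(ev)), 2)
  rows <- vector("list", ncol(idx))
  for (k in seq_len(ncol(idx))) {
    i <- idx[1, k]; j <- idx[2, k]
    if (ev$survival[i] %in% c(0, 1) || ev$survival[j] %in% c(0, 1)) {
      warn(paste0("pair (", ev$arm[i], ", ", ev$arm[j],
                  ") skipped: S(t) is 0 or 1."))
      next
    }
    z <- (ev$g[i] - ev$g[j]) / sqrt(ev$se_g[i]^2 + ev$se_g[j]^2)
    rows[[k]] <- tibble::tibble(
      arm1 = ev$arm[i], arm2 = ev$arm[j],
      survival1 = ev$survival[i], survival2 = ev$survival[j],
      z = z, p_value = 2 * pnorm(-abs(z))
    )
  }
  pairs <- dplyr::bind_rows(rows)
  structure(
    list(time = t, pairs = pairs,
         max_abs_z = if (nrow(pairs)) max(abs(pairs$z)) else NA_real_,
         n_comparisons = nrow(pairs), alpha = alpha),
    class = "homogeneity_result"
  )
}

#' @export
print.homogeneity_result <- function(x, ...) {
  cat(sprintf(
    "<homogeneity_result> S(%g) compared across %d pairs (unadjusted)\n",
    x$time, x$n_comparisons))
  print(x$pairs)
  invisible(x)
}
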
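#' Plot a Kaplan-Meier curve
#'
#' @param object A [km_estimate()] result.
#' @param conf Shade a pointwise 95% band from the Greenwood standard error?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, conf = TRUE, ...) {
  tab <- object$table
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months since surgery", y = "Disease-free survival") +
    ggplot2::theme_minimal()
  if (conf) {
    tab$lo <- pmax(tab$survival - qnorm(0.975) * tab$std_err, 0)
    tab$hi <- pmin(tab$survival + qnorm(0.975) * tab$std_err, 1)
    p <- p + ggplot2::geom_step(data = tab, ggplot2::aes(y = .data$lo),
                                linetype = "dotted") +
      ggplot2::geom_step(data = tab, ggplot2::aes(y = .data$hi),
                         linetype = "dotted")
  }
  p
}

#' Plot reconstruction fidelity
#'
#' Overlays the input digitized curve with the Kaplan-Meier curve of the
#' reconstructed patient-level data.
#'
#' @param object A [reconstruct_arm()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_reconstruction
#' @export
autoplot.km_reconstruction <- function(object, ...) {
  recon <- km_estimate(object$ipd)$table
  input <- attr(object$counts, "curve")
  ggplot2::ggplot() +
    ggplot2::geom_step(data = input,
                       ggplot2::aes(x = .data$time_months, y = .data$survival,
                                    colour = "digitized input")) +
    ggplot2::geom_step(data = recon,
                       ggplot2::aes(x = .data$time, y = .data$survival,
                                    colour = "reconstructed"),
                       linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot propensity-score overlap by treatment group
#'
#' @param object A [fit_propensity()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot propensity_model
#' @export
autoplot.propensity_model <- function(object, ...) {
  trt <- object$model$model[[object$treatment]]
  d <- tibble::tibble(
    score = object$scores,
    group = ifelse(trt == 1, "treated", "untreated")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, fill = .data$group)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(.data$density)),
                            bins = 30, position = "identity", alpha = 0.5) +
    ggplot2::labs(x = "Propensity score", y = "Density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of hazard-ratio estimates
#'
#' @param fits Named list of `cox_fit`-like objects.
#' @return A ggplot object with hazard ratios and 95% CIs on a log scale.
#' @export
plot_effect_forest <- function(fits) {
  d <- purrr::map_dfr(names(fits), function(nm) {
    f <- fits[[nm]]
    tibble::tibble(model = nm, hr = f$hr,
                   lo = f$ci_lower, hi = f$ci_upper)
  })
  d$model <- factor(d$model, levels = rev(d$model))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hr, y = .data$model)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
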
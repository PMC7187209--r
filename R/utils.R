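#' Derive a named sub-stream seed from a global seed
#'
#' Every stage of the pipeline draws its randomness from a sub-stream derived
#' deterministically from one global seed and a stage name, so that stages can
#' be re-run independently and whole runs are bit-reproducible.
#'
#' @param seed Integer global seed.
#' @param stream Character stage name, e.g. `"trial"`, `"registry"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(1, "trial")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  # multiplicative hash of the stream name folded into the seed, kept < 2^31
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 2654435 %% 2147483647) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_positive_finite <- function(x, name) {
  if (!all(is.finite(x)) || any(x <= 0)) {
    abort(paste0("`", name, "` must be finite and > 0."))
  }
  invisible(x)
}

assert_prob <- function(x, name, open = FALSE) {
  ok <- all(is.finite(x)) &&
    if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) {
    abort(paste0("`", name, "` must lie in ", if (open) "(0,1)" else "[0,1]", "."))
  }
  invisible(x)
}

#' Standardized mean differences between treated and untreated
#'
#' Balance diagnostic for the propensity-score corrections: for each covariate
#' the difference in (optionally weighted) group means divided by the pooled
#' unweighted standard deviation of the full cohort.
#'
#' @param data Cohort data frame.
#' @param covariates Character vector of numeric or 0/1 covariate columns.
#' @param treatment Name of the 0/1 treatment column.
#' @param weights Optional per-row weights.
#' @return A tibble with one row per covariate: `covariate`, `mean_treated`,
#'   `mean_control`, `smd`.
#' @export
smd_table <- function(data, covariates, treatment = "treated", weights = NULL) {
  w <- weights %||% rep(1, nrow(data))
  trt <- as.numeric(data[[treatment]]) == 1
  purrr::map_dfr(covariates, function(v) {
    x <- as.numeric_covariate(data[[v]])
    m1 <- weighted.mean(x[trt], w[trt])
    m0 <- weighted.mean(x[!trt], w[!trt])
    s <- sqrt((var(x[trt]) + var(x[!trt])) / 2)
    tibble::tibble(
      covariate = v, mean_treated = m1, mean_control = m0,
      smd = if (s > 0) (m1 - m0) / s else 0
    )
  })
}

# categorical cohort fields map onto the 0/1 coding used in the hazard and
# assignment models: sex -> male, pt_stage -> T4, site -> right
as.numeric_covariate <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.logical(x)) return(as.numeric(x))
  lev <- c("M" = 1, "F" = 0, "T4" = 1, "T3" = 0, "right" = 1, "left" = 0)
  if (all(x %in% names(lev))) return(unname(lev[x]))
  as.numeric(as.factor(x)) - 1
}
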
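#' Read and write the package's CSV interchange formats
#'
#' Patient-level data (IPD) files carry `trial_id, arm, patient_id,
#' time_months, event`; cohort files carry the registry columns
#' (`patient_id, age_years, sex, pt_stage, nodes_lt10, site, diff_poor,
#' treated, time_months, event`); digitized-curve files carry
#' `time_months, survival`; risk-table files carry `time_months, n_at_risk`.
#'
#' @param path File path.
#' @return A tibble with the validated columns.
#' @name kmpool_io
NULL

read_checked <- function(path, required) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(paste0("`", path, "` lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x
}

#' @rdname kmpool_io
#' @export
read_ipd_csv <- function(path) {
  read_checked(path, c("trial_id", "arm", "patient_id", "time_months", "event"))
}

#' @rdname kmpool_io
#' @param ipd IPD tibble.
#' @export
write_ipd_csv <- function(ipd, path) {
  readr::write_csv(ipd[c("trial_id", "arm", "patient_id", "time_months",
                         "event")], path)
  invisible(path)
}

#' @rdname kmpool_io
#' @export
read_cohort_csv <- function(path) {
  read_checked(path, c("patient_id", "age_years", "sex", "pt_stage",
                       "nodes_lt10", "site", "diff_poor", "treated",
                       "time_months", "event"))
}

#' @rdname kmpool_io
#' @param cohort Cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort[c("patient_id", "age_years", "sex", "pt_stage",
                            "nodes_lt10", "site", "diff_poor", "treated",
                            "time_months", "event")], path)
  invisible(path)
}

#' @rdname kmpool_io
#' @export
read_curve_csv <- function(path) {
  read_checked(path, c("time_months", "survival"))
}

#' @rdname kmpool_io
#' @export
read_risk_csv <- function(path) {
  read_checked(path, c("time_months", "n_at_risk"))
}
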
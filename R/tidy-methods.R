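## broom-style accessors for the pipeline's result objects.

#' @describeIn select_cohort tidy method: the cohort records as a plain
#'   tibble.
#' @param x a `hnc_cohort` object.
#' @param ... unused.
#' @export
tidy.hnc_cohort <- function(x, ...) {
  out <- x
  attr(out, "attrition") <- NULL
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @describeIn select_cohort glance method: one-row selection summary.
#' @export
glance.hnc_cohort <- function(x, ...) {
  elig <- x[x$eligible, , drop = FALSE]
  tibble(
    n_patients = nrow(x),
    n_eligible = nrow(elig),
    n_excluded = nrow(x) - nrow(elig),
    mean_age = mean(elig$age_at_index),
    pct_male = ifelse(nrow(elig) > 0,
                      round_half_up(100 * mean(elig$sex == "male"), 1), NA_real_),
    mean_eci = mean(elig$eci_score),
    median_follow_up_days = median(elig$follow_up_days)
  )
}

#' @describeIn tabulate_patterns tidy method: stratum / label / n / pct in
#'   long form.
#' @param x a `hnc_pattern_table`.
#' @param ... unused.
#' @export
tidy.hnc_pattern_table <- function(x, ...) {
  out <- x[c("stratum", "label", "n", "pct")]
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @describeIn tabulate_patterns glance method: table-level summary.
#' @export
glance.hnc_pattern_table <- function(x, ...) {
  tibble(
    by = attr(x, "by"),
    level = attr(x, "level"),
    n_strata = length(unique(x$stratum)),
    n_patients = sum(x$n)
  )
}

#' @describeIn summarize_utilization tidy method.
#' @param x a `hnc_utilization`.
#' @param ... unused.
#' @export
tidy.hnc_utilization <- function(x, ...) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @describeIn summarize_costs tidy method.
#' @param x a `hnc_cost_summary`.
#' @param ... unused.
#' @export
tidy.hnc_cost_summary <- function(x, ...) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @describeIn summarize_costs glance method: stratum totals and cost per
#'   patient-year across all categories.
#' @export
glance.hnc_cost_summary <- function(x, ...) {
  x |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      total_sum = sum(.data$total_sum),
      patient_years = .data$patient_years[1],
      cost_per_patient_year = sum(.data$total_sum) / .data$patient_years[1],
      .groups = "drop"
    )
}
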
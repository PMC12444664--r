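## Healthcare resource utilization and costs over the 12-month post-index
## window, overall and by treatment group or tumour site.

hcru_categories <- c("physician_visits", "admissions", "prescriptions",
                     "lab_tests", "imaging", "la_surgery", "radiotherapy",
                     "rehab_homecare")

#' HCRU aggregation configuration
#'
#' @param window_days length of the post-index measurement window.
#' @param require_full_window restrict to patients observed for the whole
#'   window.
#' @param cost_py_denominator denominator for cost per patient-year:
#'   `"full_followup"` divides each stratum's total expenditure by the sum
#'   of the full follow-up duration (in years, uncapped) of all its
#'   patients; `"capped_1y"` caps each patient's contribution at one year.
#' @return list of class `hnc_hcru_config`.
#' @export
hcru_config <- function(window_days = 365, require_full_window = TRUE,
                        cost_py_denominator = c("full_followup", "capped_1y")) {
  stopifnot(window_days > 0)
  structure(list(
    window_days = window_days,
    require_full_window = require_full_window,
    cost_py_denominator = match.arg(cost_py_denominator)
  ), class = "hnc_hcru_config")
}

#' Restrict a cohort to patients with full post-index observation
#'
#' @param cohort cohort records with `follow_up_days`.
#' @param config [hcru_config()].
#' @return the eligible subset (all rows when `require_full_window` is off).
#' @export
hcru_cohort <- function(cohort, config = hcru_config()) {
  out <- cohort[cohort$eligible, , drop = FALSE]
  if (config$require_full_window) {
    out <- out[out$follow_up_days >= config$window_days, , drop = FALSE]
  }
  out
}

# long event table: one row per in-window event with its HCRU category.
# Admissions overlapping the window end count in full when the admit date
# is inside the window (claims are billed at admission granularity).
hcru_event_table <- function(claims, cohort, config = hcru_config()) {
  idx <- cohort[c("patient_id", "index_date")]
  in_window <- function(tbl, date_col) {
    tbl <- dplyr::inner_join(tbl, idx, by = "patient_id")
    d <- days_between(tbl$index_date, tbl[[date_col]])
    tbl[d >= 0 & d < config$window_days, , drop = FALSE]
  }
  proc <- in_window(claims$procedures, "date")
  proc$category <- dplyr::recode(proc$category,
    physician_visit = "physician_visits", lab_test = "lab_tests",
    imaging = "imaging", rehab_homecare = "rehab_homecare",
    surgery_resection = "la_surgery", neck_dissection = "la_surgery",
    radiotherapy_fraction = "radiotherapy")
  drugs <- in_window(claims$drugs, "date")
  adm <- in_window(claims$admissions, "admit_date")
  dplyr::bind_rows(
    proc[c("patient_id", "category", "cost")],
    tibble(patient_id = drugs$patient_id, category = "prescriptions",
           cost = drugs$cost),
    tibble(patient_id = adm$patient_id, category = "admissions",
           cost = adm$cost)
  )
}

add_stratum <- function(cohort, labels, by) {
  if (by == "overall") {
    cohort$stratum <- "overall"
  } else if (by == "site") {
    cohort$stratum <- as.character(cohort$site)
  } else if (by == "primary_treatment") {
    if (is.null(labels)) abort("`labels` is required for by = \"primary_treatment\"")
    cohort$stratum <- as.character(
      labels$top[match(cohort$patient_id, labels$patient_id)])
  } else {
    abort("`by` must be one of overall, primary_treatment, site")
  }
  cohort
}

#' Summarize resource utilization per category and stratum
#'
#' Counts events per patient in the `[index, index + window)` interval and
#' summarizes among users only (patients with at least one event in the
#' category): user counts and percentages of the stratum N, and mean / SD /
#' median / min / max event counts.
#'
#' @param claims an `hnc_claims` object.
#' @param cohort the HCRU-eligible cohort (see [hcru_cohort()]).
#' @param labels optional classification labels for treatment strata.
#' @param by `"overall"`, `"primary_treatment"` or `"site"`.
#' @param config [hcru_config()].
#' @return a `hnc_utilization` tibble: one row per stratum x category.
#' @export
summarize_utilization <- function(claims, cohort, labels = NULL,
                                  by = "overall", config = hcru_config()) {
  cohort <- add_stratum(cohort, labels, by)
  events <- hcru_event_table(claims, cohort, config)
  events$stratum <- cohort$stratum[match(events$patient_id, cohort$patient_id)]
  strata_n <- dplyr::count(cohort, .data$stratum, name = "stratum_n")
  per_patient <- events |>
    dplyr::count(.data$stratum, .data$category, .data$patient_id, name = "k")
  out <- per_patient |>
    dplyr::group_by(.data$stratum, .data$category) |>
    dplyr::summarise(
      user_n = dplyr::n(),
      mean = mean(.data$k), sd = ifelse(dplyr::n() > 1, sd(.data$k), 0),
      median = median(.data$k), min = min(.data$k), max = max(.data$k),
      .groups = "drop"
    ) |>
    tidyr::complete(
      stratum = unique(cohort$stratum),
      category = factor(hcru_categories, levels = hcru_categories),
      fill = list(user_n = 0L, mean = NA_real_, sd = NA_real_,
                  median = NA_real_, min = NA_real_, max = NA_real_)
    ) |>
    dplyr::mutate(category = as.character(.data$category)) |>
    dplyr::left_join(strata_n, by = "stratum") |>
    dplyr::mutate(
      user_pct = ifelse(.data$stratum_n > 0,
                        round_half_up(100 * .data$user_n / .data$stratum_n, 1),
                        NA_real_),
      user_cell = format_count_pct(.data$user_n, pmax(.data$stratum_n, 1L)),
      empty_stratum = .data$stratum_n == 0
    ) |>
    dplyr::relocate("stratum", "category", "stratum_n", "user_n", "user_pct")
  structure(out, class = c("hnc_utilization", class(out)), by = by)
}

#' Summarize costs per category and stratum
#'
#' Per-patient category expenditure over the measurement window, summarized
#' among users (mean, SD), with the stratum total and cost per patient-year
#' (total expenditure divided by the summed follow-up duration in years of
#' the stratum's patients; see [hcru_config()] for the denominator options).
#'
#' @inheritParams summarize_utilization
#' @return a `hnc_cost_summary` tibble: one row per stratum x category with
#'   `user_n`, `mean_cost`, `sd_cost`, `total_sum`, `patient_years`,
#'   `cost_per_patient_year`.
#' @export
summarize_costs <- function(claims, cohort, labels = NULL, by = "overall",
                            config = hcru_config()) {
  cohort <- add_stratum(cohort, labels, by)
  events <- hcru_event_table(claims, cohort, config)
  events$stratum <- cohort$stratum[match(events$patient_id, cohort$patient_id)]
  fu_years <- if (config$cost_py_denominator == "full_followup") {
    cohort$follow_up_days / 365.25
  } else {
    pmin(cohort$follow_up_days, config$window_days) / 365.25
  }
  py <- tapply(fu_years, cohort$stratum, sum)
  per_patient <- events |>
    dplyr::group_by(.data$stratum, .data$category, .data$patient_id) |>
    dplyr::summarise(total = sum(as.numeric(.data$cost)), .groups = "drop")
  out <- per_patient |>
    dplyr::group_by(.data$stratum, .data$category) |>
    dplyr::summarise(
      user_n = dplyr::n(),
      mean_cost = mean(.data$total),
      sd_cost = ifelse(dplyr::n() > 1, sd(.data$total), 0),
      total_sum = sum(.data$total),
      .groups = "drop"
    ) |>
    tidyr::complete(
      stratum = unique(cohort$stratum),
      category = factor(hcru_categories, levels = hcru_categories),
      fill = list(user_n = 0L, mean_cost = NA_real_, sd_cost = NA_real_,
                  total_sum = 0)
    ) |>
    dplyr::mutate(
      category = as.character(.data$category),
      patient_years = as.numeric(py[.data$stratum]),
      cost_per_patient_year = ifelse(.data$patient_years > 0,
                                     .data$total_sum / .data$patient_years, 0)
    )
  structure(out, class = c("hnc_cost_summary", class(out)), by = by)
}
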
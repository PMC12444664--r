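## Inclusion / exclusion cascade and baseline characteristics.
##
## Inclusion: a confirmed head-and-neck cancer diagnosis (>=1 inpatient
## claim, or >=2 outpatient claims with a primary diagnosis code) during the
## diagnosis window, with a locally advanced stage claim (III/IVA/IVB)
## within 60 days. The index date is the earliest such diagnosis date.
## Exclusions, in cascade order (the single recorded reason is the first
## failing criterion): age < 18 at index; any metastatic-disease code
## (C78.x/C79.x) before index; any stage I/II/IVC claim before index; any
## other primary cancer in the pre-index year; less than 12 months of
## pre-index enrollment; chemotherapy as the only treatment (unless a neck
## dissection was also performed); clinical-trial participation.

exclusion_reasons <- c("no_confirmed_dx", "no_valid_stage", "age",
                       "prior_metastasis", "prior_other_stage",
                       "other_primary_cancer", "insufficient_pre_index",
                       "chemo_only", "clinical_trial")

age_bands <- c("<=55", "55-65", "65-75", ">75")

#' Cohort-selection configuration
#'
#' @param diagnosis_window Date pair inside which the index diagnosis must
#'   fall.
#' @param staging_window_days max days between the index diagnosis and a
#'   locally advanced stage claim (applied as an unsigned difference).
#' @param pre_index_days required pre-index enrollment, days.
#' @param min_age minimum age at index.
#' @param treated_window_days window for the chemotherapy-only check.
#' @return list of class `hnc_selection_config`.
#' @export
selection_config <- function(diagnosis_window = as.Date(c("2016-01-01",
                                                          "2021-06-30")),
                             staging_window_days = 60,
                             pre_index_days = 365,
                             min_age = 18,
                             treated_window_days = 183) {
  structure(list(
    diagnosis_window = as.Date(diagnosis_window),
    staging_window_days = staging_window_days,
    pre_index_days = pre_index_days,
    min_age = min_age,
    treated_window_days = treated_window_days
  ), class = "hnc_selection_config")
}

#' Determine a patient's index date
#'
#' The earliest head-and-neck cancer diagnosis date inside the diagnosis
#' window that (a) satisfies the confirmation rule — the claim is inpatient,
#' or it is an outpatient primary-diagnosis claim and the patient has at
#' least two such claims — and (b) has a stage III/IVA/IVB claim within
#' `staging_window_days` of it.
#'
#' @param diagnoses one patient's diagnosis claims (`date`, `icd10`,
#'   `setting`, `primary_dx`).
#' @param staging one patient's staging claims (`date`, `stage`).
#' @param config [selection_config()].
#' @return the index date, or `NA` with attribute `why` (`"no_confirmed_dx"`
#'   or `"no_valid_stage"`) when no date qualifies.
#' @export
determine_index_date <- function(diagnoses, staging,
                                 config = selection_config()) {
  hnc <- diagnoses[is_hnc_code(diagnoses$icd10), , drop = FALSE]
  n_outpatient_primary <- sum(hnc$setting == "outpatient" & hnc$primary_dx)
  confirmed <- hnc$setting == "inpatient" |
    (hnc$setting == "outpatient" & hnc$primary_dx & n_outpatient_primary >= 2)
  in_window <- hnc$date >= config$diagnosis_window[1] &
    hnc$date <= config$diagnosis_window[2]
  candidates <- sort(unique(hnc$date[confirmed & in_window]))
  if (length(candidates) == 0) {
    return(structure(as.Date(NA), why = "no_confirmed_dx"))
  }
  la_dates <- staging$date[staging$stage %in% la_stages]
  for (d in candidates) {
    d <- as.Date(d, origin = "1970-01-01")
    if (any(abs(days_between(d, la_dates)) <= config$staging_window_days)) {
      return(d)
    }
  }
  structure(as.Date(NA), why = "no_valid_stage")
}

# Tumour site implied by the HNC diagnosis codes at (or nearest) index.
site_from_codes <- function(codes) {
  for (site in names(hnc_code_prefixes)) {
    if (any(icd_matches(codes, hnc_code_prefixes[[site]]))) return(site)
  }
  NA_character_
}

#' Apply the exclusion cascade to one patient
#'
#' Evaluates the exclusion criteria in cascade order against a determined
#' index date and reports the first failure, if any.
#'
#' @param patient one row of the patients table.
#' @param diagnoses,staging one patient's claims.
#' @param index_date the determined index date.
#' @param timeline the patient's `hnc_timeline` (used by the
#'   chemotherapy-only rule); may be `NULL` to skip that rule.
#' @param config [selection_config()].
#' @return `NA_character_` when eligible, else the exclusion reason.
#' @export
apply_exclusions <- function(patient, diagnoses, staging, index_date,
                             timeline = NULL, config = selection_config()) {
  age <- as.integer(format(index_date, "%Y")) - patient$birth_year
  if (age < config$min_age) return("age")

  before_index <- diagnoses$date < index_date
  if (any(before_index & icd_matches(diagnoses$icd10, metastasis_prefixes))) {
    return("prior_metastasis")
  }
  if (any(staging$date < index_date &
          staging$stage %in% c("I", "II", "IVC"))) {
    return("prior_other_stage")
  }
  pre_index <- before_index &
    days_between(diagnoses$date, index_date) <= config$pre_index_days
  other_cancer <- startsWith(diagnoses$icd10, "C") &
    !is_hnc_code(diagnoses$icd10) &
    !icd_matches(diagnoses$icd10, metastasis_prefixes)
  if (any(pre_index & other_cancer)) return("other_primary_cancer")

  if (days_between(patient$enroll_start, index_date) < config$pre_index_days) {
    return("insufficient_pre_index")
  }
  if (!is.null(timeline) && timeline$treated &&
      nrow(timeline$blocks) > 0 &&
      all(timeline$blocks$modality == "systemic") &&
      !timeline$has_neck_dissection) {
    return("chemo_only")
  }
  if (isTRUE(patient$clinical_trial)) return("clinical_trial")
  NA_character_
}

#' Build the analysis cohort from raw claims
#'
#' Runs index-date determination, the exclusion cascade, baseline
#' characteristics and Elixhauser scoring for every patient, returning one
#' record per patient. The attrition counts of the cascade are attached as
#' an attribute (see [attrition_log()]).
#'
#' @param claims an `hnc_claims` object.
#' @param config [selection_config()].
#' @param windows [window_config()] used for the chemotherapy-only rule.
#' @param eci_mapping weight table from [eci_weights()].
#' @return a `hnc_cohort` tibble: `patient_id`, `index_date`, `eligible`,
#'   `exclusion_reason`, `age_at_index`, `age_band`, `sex`, `site`, `stage`,
#'   `lymph_node`, `eci_score`, `follow_up_days`.
#' @export
select_cohort <- function(claims, config = selection_config(),
                          windows = window_config(),
                          eci_mapping = eci_weights()) {
  stopifnot(inherits(claims, "hnc_claims"))
  pts <- claims$patients
  dx_split <- split(claims$diagnoses, claims$diagnoses$patient_id)
  st_split <- split(claims$staging, claims$staging$patient_id)
  empty_dx <- claims$diagnoses[0, ]
  empty_st <- claims$staging[0, ]

  n <- nrow(pts)
  index_date <- as.Date(rep(NA, n))
  reason <- rep(NA_character_, n)
  site <- rep(NA_character_, n)
  stage <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    dx <- dx_split[[pts$patient_id[i]]] %||% empty_dx
    st <- st_split[[pts$patient_id[i]]] %||% empty_st
    idx <- determine_index_date(dx, st, config)
    if (is.na(idx)) {
      reason[i] <- attr(idx, "why")
      next
    }
    index_date[i] <- idx
    # stage = the locally advanced stage claim nearest the index date
    la <- st[st$stage %in% la_stages, , drop = FALSE]
    gap <- abs(days_between(idx, la$date))
    la <- la[gap <= config$staging_window_days, , drop = FALSE]
    ord <- order(abs(days_between(idx, la$date)), la$date, method = "radix")
    stage[i] <- la$stage[ord[1]]
    site[i] <- site_from_codes(dx$icd10[is_hnc_code(dx$icd10) & dx$date == idx])
    if (is.na(site[i])) site[i] <- site_from_codes(dx$icd10[is_hnc_code(dx$icd10)])
  }

  # episode timelines are needed only for the chemotherapy-only rule
  has_index <- which(!is.na(index_date))
  timelines <- derive_timelines(
    claims,
    tibble(patient_id = pts$patient_id[has_index],
           index_date = index_date[has_index]),
    windows
  )
  tl_map <- setNames(timelines$timeline, timelines$patient_id)

  for (i in has_index) {
    reason[i] <- apply_exclusions(
      pts[i, , drop = FALSE],
      dx_split[[pts$patient_id[i]]] %||% empty_dx,
      st_split[[pts$patient_id[i]]] %||% empty_st,
      index_date[i],
      timeline = tl_map[[pts$patient_id[i]]],
      config = config
    )
  }

  eci <- compute_eci(claims$diagnoses,
                     tibble(patient_id = pts$patient_id, index_date = index_date),
                     mapping = eci_mapping,
                     pre_index_days = config$pre_index_days)
  age <- as.integer(format(index_date, "%Y")) - pts$birth_year
  cohort <- tibble(
    patient_id = pts$patient_id,
    index_date = index_date,
    eligible = is.na(reason),
    exclusion_reason = factor(reason, levels = exclusion_reasons),
    age_at_index = age,
    age_band = factor(ifelse(is.na(age), NA_character_,
                        ifelse(age <= 55, "<=55",
                        ifelse(age <= 65, "55-65",
                        ifelse(age <= 75, "65-75", ">75")))),
                      levels = age_bands),
    sex = pts$sex,
    site = factor(site, levels = hnc_sites),
    stage = factor(stage, levels = la_stages),
    lymph_node = "unknown",
    eci_score = eci$eci_score[match(pts$patient_id, eci$patient_id)],
    follow_up_days = days_between(index_date, pts$enroll_end)
  )
  cohort$eligible[is.na(cohort$index_date)] <- FALSE
  structure(cohort, class = c("hnc_cohort", class(cohort)),
            attrition = compute_attrition(cohort))
}

compute_attrition <- function(cohort) {
  n <- nrow(cohort)
  steps <- c("all_patients", exclusion_reasons)
  remaining <- integer(length(steps))
  remaining[1] <- n
  excluded <- integer(length(steps)); excluded[1] <- 0L
  still_in <- rep(TRUE, n)
  for (k in seq_along(exclusion_reasons)) {
    hit <- !is.na(cohort$exclusion_reason) &
      cohort$exclusion_reason == exclusion_reasons[k]
    excluded[k + 1] <- sum(hit)
    still_in <- still_in & !hit
    remaining[k + 1] <- sum(still_in)
  }
  tibble(step = steps, excluded = excluded, remaining = remaining)
}

#' Attrition counts for the selection cascade
#'
#' Ordered counts of patients surviving each filter, ending at the eligible
#' N; counts are non-increasing by construction.
#'
#' @param cohort output of [select_cohort()].
#' @param path optional path: when given the log is also written as JSON.
#' @return tibble with `step`, `excluded`, `remaining`.
#' @export
attrition_log <- function(cohort, path = NULL) {
  log <- attr(cohort, "attrition") %||% compute_attrition(cohort)
  if (!is.null(path)) {
    jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA)
  }
  log
}

#' Baseline characteristics table
#'
#' Summaries in the shape of a baseline-characteristics table: mean / SD /
#' median / min / max for age and follow-up, counts and percentages for age
#' bands, sex, site and stage. A single-patient stratum reports SD 0 with a
#' flag; an empty cohort returns the empty sentinel shape rather than
#' failing.
#'
#' @param cohort eligible cohort records.
#' @return tibble with `variable`, `level`, `statistic`, `value`, `cell`.
#' @export
baseline_table <- function(cohort) {
  cohort <- cohort[cohort$eligible, , drop = FALSE]
  n <- nrow(cohort)
  rows <- list()
  num_summary <- function(variable, x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(tibble(variable = variable, level = NA_character_,
                    statistic = c("n"), value = 0,
                    cell = "0"))
    }
    sd_val <- if (length(x) > 1) sd(x) else 0
    tibble(
      variable = variable, level = NA_character_,
      statistic = c("n", "mean", "sd", "median", "min", "max"),
      value = c(length(x), mean(x), sd_val, median(x), min(x), max(x)),
      cell = c(sprintf("%d", length(x)),
               sprintf("%.1f", mean(x)),
               if (length(x) > 1) sprintf("%.1f", sd_val) else "0 (single patient)",
               sprintf("%.1f", median(x)),
               sprintf("%.1f", min(x)), sprintf("%.1f", max(x)))
    )
  }
  cat_summary <- function(variable, x, levels) {
    counts <- table(factor(x, levels = levels))
    tibble(
      variable = variable, level = levels,
      statistic = "n_pct", value = as.numeric(counts),
      cell = format_count_pct(as.integer(counts), max(n, 1L))
    )
  }
  rows$age <- num_summary("age_years", cohort$age_at_index)
  rows$fu <- num_summary("follow_up_days", cohort$follow_up_days)
  rows$band <- cat_summary("age_band", cohort$age_band, age_bands)
  rows$sex <- cat_summary("sex", cohort$sex, c("male", "female"))
  rows$site <- cat_summary("site", cohort$site, hnc_sites)
  rows$stage <- cat_summary("stage", cohort$stage, la_stages)
  rows$eci <- num_summary("eci_score", cohort$eci_score)
  dplyr::bind_rows(rows)
}
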
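## Elixhauser Comorbidity Index.
##
## 30 comorbidity categories flagged from ICD-10 code prefixes (Quan's
## ICD-10 coding of the Elixhauser measures, with the two hypertension
## categories combined) and scored with van Walraven's weights, giving the
## attainable range -19 (all negatively weighted categories) to +89 (all
## positively weighted ones).

#' Load the Elixhauser category/weight table
#'
#' The mapping ships as a plain-text CSV (`eci_weights.csv`) with one row per
#' comorbidity category: its van Walraven weight and the semicolon-separated
#' ICD-10 prefixes that flag it. The file is user-editable; a replacement
#' path can be supplied for alternative weightings.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return tibble with `category`, `weight` and a list-column `prefixes`.
#' @export
eci_weights <- function(path = NULL) {
  path <- path %||% system.file("extdata", "eci_weights.csv",
                                package = "hncpatterns", mustWork = TRUE)
  tbl <- readr::read_csv(path, col_types = readr::cols(
    category = readr::col_character(),
    weight = readr::col_integer(),
    icd10_prefixes = readr::col_character()
  ), progress = FALSE)
  tbl$prefixes <- strsplit(tbl$icd10_prefixes, ";", fixed = TRUE)
  tbl[c("category", "weight", "prefixes")]
}

#' Score the Elixhauser Comorbidity Index from pre-index diagnoses
#'
#' A category is flagged when any diagnosis claim dated strictly before the
#' index date (and within the pre-index window) carries an ICD-10 code
#' matching one of its prefixes; the score is the sum of flagged category
#' weights. Duplicate codes within a category count once.
#'
#' @param diagnoses tibble of diagnosis claims (`patient_id`, `date`,
#'   `icd10`) for one or many patients.
#' @param index_dates tibble with `patient_id` and `index_date`.
#' @param mapping weight table from [eci_weights()].
#' @param pre_index_days length of the look-back window in days.
#' @return tibble with `patient_id`, `eci_score`, and a list-column
#'   `eci_categories` of flagged category names.
#' @export
compute_eci <- function(diagnoses, index_dates, mapping = eci_weights(),
                        pre_index_days = 365) {
  stopifnot(all(c("patient_id", "index_date") %in% names(index_dates)))
  out <- tibble(
    patient_id = index_dates$patient_id,
    eci_score = 0L,
    eci_categories = vector("list", nrow(index_dates))
  )
  if (nrow(diagnoses) > 0) {
    dx <- dplyr::inner_join(
      diagnoses[c("patient_id", "date", "icd10")],
      index_dates[c("patient_id", "index_date")],
      by = "patient_id"
    )
    delta <- days_between(dx$date, dx$index_date)
    dx <- dx[delta > 0 & delta <= pre_index_days, , drop = FALSE]
    if (nrow(dx) > 0) {
      code <- icd_normalize(dx$icd10)
      for (i in seq_len(nrow(mapping))) {
        hit <- rep(FALSE, nrow(dx))
        for (p in icd_normalize(mapping$prefixes[[i]])) {
          hit <- hit | startsWith(code, p)
        }
        if (!any(hit)) next
        pts <- unique(dx$patient_id[hit])
        j <- match(pts, out$patient_id)
        out$eci_score[j] <- out$eci_score[j] + mapping$weight[i]
        for (k in j) {
          out$eci_categories[[k]] <- c(out$eci_categories[[k]],
                                       mapping$category[i])
        }
      }
    }
  }
  out$eci_categories <- lapply(out$eci_categories, function(x) x %||% character(0))
  out
}
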
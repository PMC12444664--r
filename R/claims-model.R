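## Claims data model: six related tables keyed by patient_id.
##
## patients    patient_id, birth_year, sex, enroll_start, enroll_end,
##             death_date (optional), clinical_trial
## diagnoses   patient_id, date, icd10, setting, primary_dx
## staging     patient_id, date, stage
## drugs       patient_id, date, agent, atc (optional), cost
## procedures  patient_id, date, category, cost
## admissions  patient_id, admit_date, discharge_date, cost, died_in_hospital

claims_table_names <- c("patients", "diagnoses", "staging", "drugs",
                        "procedures", "admissions")

claims_schemas <- list(
  patients = c(patient_id = "character", birth_year = "integer",
               sex = "character", enroll_start = "Date", enroll_end = "Date",
               death_date = "Date", clinical_trial = "logical"),
  diagnoses = c(patient_id = "character", date = "Date", icd10 = "character",
                setting = "character", primary_dx = "logical"),
  staging = c(patient_id = "character", date = "Date", stage = "character"),
  drugs = c(patient_id = "character", date = "Date", agent = "character",
            atc = "character", cost = "integer"),
  procedures = c(patient_id = "character", date = "Date",
                 category = "character", cost = "integer"),
  admissions = c(patient_id = "character", admit_date = "Date",
                 discharge_date = "Date", cost = "integer",
                 died_in_hospital = "logical")
)

empty_claims_table <- function(name) {
  schema <- claims_schemas[[name]]
  cols <- lapply(schema, function(type) {
    switch(type,
      character = character(0),
      integer = integer(0),
      logical = logical(0),
      Date = as.Date(character(0))
    )
  })
  tibble::as_tibble(cols)
}

date_col <- function(name) if (name == "admissions") "admit_date" else "date"

canonical_sort <- function(tbl, name) {
  if (name == "patients") {
    return(tbl[order(tbl$patient_id, method = "radix"), , drop = FALSE])
  }
  # full-column tiebreak so the order is a pure function of the row set
  key <- date_col(name)
  rest <- setdiff(names(tbl), c("patient_id", key))
  keys <- c(list(tbl$patient_id, tbl[[key]]),
            lapply(tbl[rest], function(col) {
              if (is.numeric(col)) col else as.character(col)
            }))
  tbl[do.call(order, c(keys, list(method = "radix"))), , drop = FALSE]
}

#' Assemble a claims object from its component tables
#'
#' Bundles the six claims tables into a single validated object. Missing
#' tables default to empty tables with the right schema; all event tables are
#' put into canonical order (patient, date, stable input order) so every
#' downstream stage is invariant to input row shuffling.
#'
#' @param patients,diagnoses,staging,drugs,procedures,admissions tibbles
#'   conforming to the documented schemas.
#' @param validate run invariant checks (recommended).
#' @return an object of class `hnc_claims`: a named list of six tibbles.
#' @export
claims_tables <- function(patients = NULL, diagnoses = NULL, staging = NULL,
                          drugs = NULL, procedures = NULL, admissions = NULL,
                          validate = TRUE) {
  supplied <- list(patients = patients, diagnoses = diagnoses,
                   staging = staging, drugs = drugs, procedures = procedures,
                   admissions = admissions)
  tables <- lapply(claims_table_names, function(name) {
    tbl <- supplied[[name]]
    if (is.null(tbl)) return(empty_claims_table(name))
    tbl <- tibble::as_tibble(tbl)
    schema <- claims_schemas[[name]]
    missing <- setdiff(names(schema), names(tbl))
    # optional columns get typed NA defaults; truly required ones must exist
    optional <- intersect(missing, c("death_date", "atc", "clinical_trial"))
    for (col in optional) {
      tbl[[col]] <- switch(claims_schemas[[name]][[col]],
        Date = as.Date(NA), character = NA_character_, logical = FALSE)
    }
    missing <- setdiff(names(schema), names(tbl))
    if (length(missing) > 0) {
      abort(sprintf("table `%s` is missing required column(s): %s",
                    name, paste(missing, collapse = ", ")))
    }
    tbl <- tbl[names(schema)]
    for (col in names(schema)) {
      tbl[[col]] <- switch(schema[[col]],
        character = as.character(tbl[[col]]),
        integer = as.integer(tbl[[col]]),
        logical = as.logical(tbl[[col]]),
        Date = as.Date(tbl[[col]])
      )
    }
    canonical_sort(tbl, name)
  })
  names(tables) <- claims_table_names
  out <- structure(tables, class = "hnc_claims")
  if (validate) validate_claims(out)
  out
}

#' @export
print.hnc_claims <- function(x, ...) {
  cat("<hnc_claims> ", nrow(x$patients), " patients\n", sep = "")
  for (name in claims_table_names) {
    cat(sprintf("  %-11s %6d rows\n", name, nrow(x[[name]])))
  }
  invisible(x)
}

#' Validate a claims object against the model invariants
#'
#' Checks enum membership, ICD-10 code shape, non-negative costs, ordered
#' enrollment and admission spans, and that every event falls inside its
#' patient's enrollment span. Violations are reported with patient ids and
#' row numbers.
#'
#' @param claims an `hnc_claims` object.
#' @return the claims object, invisibly; errors on the first violation set.
#' @export
validate_claims <- function(claims) {
  stopifnot(inherits(claims, "hnc_claims"))
  problems <- character(0)
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))

  pt <- claims$patients
  if (anyDuplicated(pt$patient_id) > 0) {
    note("duplicated patient_id in patients: %s",
         paste(unique(pt$patient_id[duplicated(pt$patient_id)]), collapse = ", "))
  }
  bad <- which(pt$enroll_start > pt$enroll_end)
  for (i in head(bad, 5)) {
    note("patients row %d (%s): enroll_start after enroll_end", i, pt$patient_id[i])
  }
  bad <- which(!is.na(pt$death_date) &
               (pt$death_date < pt$enroll_start | pt$death_date > pt$enroll_end))
  for (i in head(bad, 5)) {
    note("patients row %d (%s): death_date outside enrollment", i, pt$patient_id[i])
  }
  bad <- which(!pt$sex %in% c("male", "female"))
  for (i in head(bad, 5)) {
    note("patients row %d: sex must be one of male, female (got %s)",
         i, pt$sex[i])
  }

  check_enum <- function(tbl, name, col, allowed) {
    bad <- which(!tbl[[col]] %in% allowed)
    for (i in head(bad, 5)) {
      note("%s row %d: %s must be one of %s (got %s)",
           name, i, col, paste(allowed, collapse = ", "), tbl[[col]][i])
    }
  }
  check_enum(claims$diagnoses, "diagnoses", "setting", c("inpatient", "outpatient"))
  check_enum(claims$staging, "staging", "stage", stage_levels)
  check_enum(claims$drugs, "drugs", "agent", agent_vocabulary)
  check_enum(claims$procedures, "procedures", "category", procedure_categories)

  bad <- which(!grepl("^[A-Z][0-9]{2}(\\.[0-9A-Za-z]{1,4})?$", claims$diagnoses$icd10))
  for (i in head(bad, 5)) {
    note("diagnoses row %d: malformed ICD-10 code %s", i, claims$diagnoses$icd10[i])
  }

  for (name in c("drugs", "procedures", "admissions")) {
    bad <- which(is.na(claims[[name]]$cost) | claims[[name]]$cost < 0)
    for (i in head(bad, 5)) note("%s row %d: cost must be a non-negative integer", name, i)
  }
  bad <- which(claims$admissions$admit_date > claims$admissions$discharge_date)
  for (i in head(bad, 5)) note("admissions row %d: admit_date after discharge_date", i)

  # events must fall inside the patient's enrollment span
  span <- setNames(split(pt[c("enroll_start", "enroll_end")], seq_len(nrow(pt))),
                   pt$patient_id)
  for (name in setdiff(claims_table_names, "patients")) {
    tbl <- claims[[name]]
    if (nrow(tbl) == 0) next
    key <- date_col(name)
    idx <- match(tbl$patient_id, pt$patient_id)
    unknown <- which(is.na(idx))
    for (i in head(unknown, 5)) {
      note("%s row %d: unknown patient_id %s", name, i, tbl$patient_id[i])
    }
    known <- which(!is.na(idx))
    out_of_span <- known[tbl[[key]][known] < pt$enroll_start[idx[known]] |
                           tbl[[key]][known] > pt$enroll_end[idx[known]]]
    for (i in head(out_of_span, 5)) {
      note("%s row %d: patient %s has event on %s outside enrollment span",
           name, i, tbl$patient_id[i], format(tbl[[key]][i]))
    }
  }

  if (length(problems) > 0) {
    abort(c("invalid claims data:", setNames(problems, rep("x", length(problems)))))
  }
  invisible(claims)
}

#' Read claims tables from a directory of CSV files
#'
#' Expects `patients.csv`, `diagnoses.csv`, `staging.csv`, `drugs.csv`,
#' `procedures.csv` and `admissions.csv` (UTF-8, comma-separated, header row,
#' ISO-8601 dates). Unknown drug names are mapped to agent `"other"` with a
#' warning rather than dropped, so all-cause prescription counts are
#' preserved.
#'
#' @param dir directory containing the six CSV files.
#' @param validate run invariant checks after reading.
#' @return an `hnc_claims` object.
#' @export
read_claims <- function(dir, validate = TRUE) {
  paths <- file.path(dir, paste0(claims_table_names, ".csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("missing claims file(s): %s", paste(missing, collapse = ", ")))
  }
  tables <- lapply(claims_table_names, function(name) {
    schema <- claims_schemas[[name]]
    spec <- do.call(readr::cols, lapply(schema, function(type) {
      switch(type,
        character = readr::col_character(),
        integer = readr::col_integer(),
        logical = readr::col_logical(),
        Date = readr::col_date(format = "%Y-%m-%d")
      )
    }))
    tbl <- readr::read_csv(file.path(dir, paste0(name, ".csv")),
                           col_types = spec, progress = FALSE)
    parse_problems <- readr::problems(tbl)
    if (nrow(parse_problems) > 0) {
      abort(c(sprintf("malformed rows in %s.csv:", name),
              setNames(sprintf("row %d: expected %s in column %d",
                               parse_problems$row, parse_problems$expected,
                               parse_problems$col),
                       rep("x", nrow(parse_problems)))))
    }
    if (name == "drugs" && any(!tbl$agent %in% agent_vocabulary)) {
      unknown <- unique(tbl$agent[!tbl$agent %in% agent_vocabulary])
      warn(sprintf("drugs.csv: unknown agent(s) mapped to \"other\": %s",
                   paste(unknown, collapse = ", ")))
      tbl$agent[!tbl$agent %in% agent_vocabulary] <- "other"
    }
    tbl
  })
  names(tables) <- claims_table_names
  do.call(claims_tables, c(tables, list(validate = validate)))
}

#' Write claims tables to a directory of CSV files
#'
#' Writes the six tables in canonical row order so identical inputs produce
#' byte-identical files.
#'
#' @param claims an `hnc_claims` object.
#' @param dir output directory (created if needed).
#' @return the paths written, invisibly.
#' @export
write_claims <- function(claims, dir) {
  stopifnot(inherits(claims, "hnc_claims"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (name in claims_table_names) {
    path <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(canonical_sort(claims[[name]], name), path, progress = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Format a count table as an "n (%)" report
#'
#' Turns a tibble of labelled counts into report rows with `n (pct)` cells,
#' percentages at one decimal (rounded half-up) of the stratum denominator.
#'
#' @param counts tibble with a `label` column and an `n` column; an optional
#'   `stratum` column defines per-stratum denominators.
#' @param total denominator; defaults to the (per-stratum) sum of `n`.
#' @return tibble with `label`, `n`, `pct` and formatted `cell` columns.
#' @export
report_counts <- function(counts, total = NULL) {
  stopifnot(all(c("label", "n") %in% names(counts)))
  if (!"stratum" %in% names(counts)) counts$stratum <- "overall"
  counts |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(
      total = .env$total %||% sum(.data$n),
      pct = ifelse(.data$total > 0,
                   round_half_up(100 * .data$n / .data$total, 1), 0),
      cell = format_count_pct(.data$n, .data$total)
    ) |>
    dplyr::ungroup()
}

#' Write a report table as TSV
#'
#' @param table a tibble (typically from [report_counts()],
#'   [tabulate_patterns()] or the utilization summaries).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}
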
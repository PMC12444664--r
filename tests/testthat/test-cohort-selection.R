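test_that("index date follows the confirmation and staging rules", {
  # inpatient claim with stage within the 60-day window
  idx <- determine_index_date(
    dx_row(date = "2018-03-01", icd10 = "C32.0", setting = "inpatient"),
    stage_row(date = "2018-03-20", stage = "III")
  )
  expect_equal(idx, as.Date("2018-03-01"), ignore_attr = TRUE)

  # a single outpatient primary claim does not confirm the diagnosis
  one_op <- determine_index_date(
    dx_row(date = "2019-01-10", icd10 = "C10.9", setting = "outpatient"),
    stage_row(date = "2019-01-20", stage = "IVA")
  )
  expect_true(is.na(one_op))
  expect_equal(attr(one_op, "why"), "no_confirmed_dx")

  # two outpatient primary claims: index at the first
  two_op <- determine_index_date(
    rbind(dx_row(date = "2019-01-10", icd10 = "C10.9", setting = "outpatient"),
          dx_row(date = "2019-02-01", icd10 = "C10.9", setting = "outpatient")),
    stage_row(date = "2019-02-15", stage = "IVA")
  )
  expect_equal(two_op, as.Date("2019-01-10"), ignore_attr = TRUE)

  # stage claim beyond 60 days does not validate the diagnosis
  far_stage <- determine_index_date(
    dx_row(date = "2018-03-01", setting = "inpatient"),
    stage_row(date = "2018-06-01", stage = "III")
  )
  expect_true(is.na(far_stage))
  expect_equal(attr(far_stage, "why"), "no_valid_stage")

  # only non-advanced stages never qualify
  expect_true(is.na(determine_index_date(
    dx_row(date = "2018-03-01", setting = "inpatient"),
    stage_row(date = "2018-03-10", stage = "II")
  )))
})

test_that("exclusions fire in cascade order with hand-built defects", {
  idx <- as.Date("2019-06-01")
  base_dx <- dx_row(date = idx)
  base_st <- stage_row(date = idx)

  minor <- patient_row(birth_year = 2005L)
  expect_equal(apply_exclusions(minor, base_dx, base_st, idx), "age")

  mets <- rbind(base_dx, dx_row(date = idx - 30, icd10 = "C78.0",
                                setting = "outpatient", primary_dx = FALSE))
  expect_equal(apply_exclusions(patient_row(), mets, base_st, idx),
               "prior_metastasis")

  early_stage <- rbind(base_st, stage_row(date = idx - 90, stage = "I"))
  expect_equal(apply_exclusions(patient_row(), base_dx, early_stage, idx),
               "prior_other_stage")

  other_ca <- rbind(base_dx, dx_row(date = idx - 60, icd10 = "C61",
                                    setting = "outpatient", primary_dx = FALSE))
  expect_equal(apply_exclusions(patient_row(), other_ca, base_st, idx),
               "other_primary_cancer")

  short_pre <- patient_row(enroll_start = "2019-01-01")
  expect_equal(apply_exclusions(short_pre, base_dx, base_st, idx),
               "insufficient_pre_index")

  trial <- patient_row(clinical_trial = TRUE)
  expect_equal(apply_exclusions(trial, base_dx, base_st, idx), "clinical_trial")

  expect_true(is.na(apply_exclusions(patient_row(), base_dx, base_st, idx)))

  # a defect earlier in the cascade masks later ones
  both <- apply_exclusions(minor, mets, base_st, idx)
  expect_equal(both, "age")
})

test_that("chemotherapy-only patients are excluded unless neck dissection was done", {
  idx <- "2019-06-01"
  chemo_only <- indexed_claims(
    index = idx,
    drugs = rbind(drug_row(date = "2019-06-10"), drug_row(date = "2019-07-01")))
  cohort <- select_cohort(chemo_only)
  expect_false(cohort$eligible)
  expect_equal(as.character(cohort$exclusion_reason), "chemo_only")

  with_nd <- indexed_claims(
    index = idx,
    drugs = rbind(drug_row(date = "2019-06-10"), drug_row(date = "2019-07-01")),
    procedures = proc_row(date = "2019-07-20", category = "neck_dissection"))
  cohort_nd <- select_cohort(with_nd)
  expect_true(cohort_nd$eligible)
})

test_that("baseline table reproduces stage percentages from printed counts", {
  counts <- c(III = 2266, IVA = 3577, IVB = 898)
  cells <- format_count_pct(counts, sum(counts))
  expect_equal(cells, c("2266 (33.6)", "3577 (53.1)", "898 (13.3)"))

  sim <- generate_cohort(generator_config(n_patients = 120, seed = 66,
                                          hcru_enabled = FALSE))
  cohort <- select_cohort(sim$claims)
  tbl <- baseline_table(cohort)
  bands <- tbl[tbl$variable == "age_band", ]
  expect_equal(sum(bands$value), sum(cohort$eligible))
  expect_equal(sum(tbl$value[tbl$variable == "stage"]), sum(cohort$eligible))

  single <- baseline_table(cohort[match(TRUE, cohort$eligible), , drop = FALSE])
  age <- single[single$variable == "age_years", ]
  expect_equal(age$value[age$statistic == "mean"],
               age$value[age$statistic == "median"])
  expect_match(age$cell[age$statistic == "sd"], "single patient")

  empty <- baseline_table(cohort[0, , drop = FALSE])
  expect_s3_class(empty, "tbl_df")
})

test_that("attrition is monotone and matches the generator truth per reason", {
  sim <- generate_cohort(generator_config(n_patients = 400, seed = 24,
                                          hcru_enabled = FALSE))
  cohort <- select_cohort(sim$claims)
  log <- attrition_log(cohort)
  expect_true(all(diff(log$remaining) <= 0))
  expect_equal(log$remaining[nrow(log)], sum(cohort$eligible))

  truth_reason <- ifelse(sim$truth$contaminant == "under_18", "age",
                         sim$truth$contaminant)
  truth_counts <- table(truth_reason[truth_reason != "none"])
  derived <- table(as.character(cohort$exclusion_reason))
  for (r in names(truth_counts)) {
    expect_equal(unname(derived[r]), unname(truth_counts[r]), ignore_attr = TRUE,
                 label = sprintf("count for %s", r))
  }
  # verdict closure: 100% agreement with the truth table
  joined <- dplyr::inner_join(tidy(cohort), sim$truth, by = "patient_id")
  expect_equal(joined$eligible.x, joined$eligible.y)

  # a clean cohort loses nobody
  clean <- generate_cohort(generator_config(n_patients = 50, seed = 2,
                                            contaminant_probs = c(under_18 = 0),
                                            hcru_enabled = FALSE))
  clean_log <- attrition_log(select_cohort(clean$claims))
  expect_true(all(clean_log$remaining == 50))
})

test_that("verdicts are invariant under claim-row shuffling", {
  sim <- generate_cohort(generator_config(n_patients = 50, seed = 13,
                                          hcru_enabled = FALSE))
  cohort1 <- select_cohort(sim$claims)
  set.seed(1)
  shuffled <- claims_tables(
    patients = sim$claims$patients[sample.int(nrow(sim$claims$patients)), ],
    diagnoses = sim$claims$diagnoses[sample.int(nrow(sim$claims$diagnoses)), ],
    staging = sim$claims$staging[sample.int(nrow(sim$claims$staging)), ],
    drugs = sim$claims$drugs[sample.int(nrow(sim$claims$drugs)), ],
    procedures = sim$claims$procedures[sample.int(nrow(sim$claims$procedures)), ],
    admissions = sim$claims$admissions,
    validate = FALSE
  )
  cohort2 <- select_cohort(shuffled)
  j <- dplyr::inner_join(tidy(cohort1), tidy(cohort2), by = "patient_id")
  expect_equal(j$eligible.x, j$eligible.y)
  expect_equal(j$index_date.x, j$index_date.y)
  expect_equal(j$eci_score.x, j$eci_score.y)
})

test_that("ECI scores of a generated cohort stay within analytic bounds", {
  sim <- generate_cohort(generator_config(n_patients = 200, seed = 88,
                                          hcru_enabled = FALSE))
  cohort <- select_cohort(sim$claims)
  expect_true(all(cohort$eci_score >= -19 & cohort$eci_score <= 89,
                  na.rm = TRUE))
})
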
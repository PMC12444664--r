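# Builders for small hand-traced claims fixtures.

patient_row <- function(id = "P1", birth_year = 1955L, sex = "male",
                        enroll_start = "2015-06-01", enroll_end = "2021-12-31",
                        clinical_trial = FALSE) {
  data.frame(patient_id = id, birth_year = as.integer(birth_year), sex = sex,
             enroll_start = as.Date(enroll_start),
             enroll_end = as.Date(enroll_end),
             death_date = as.Date(NA), clinical_trial = clinical_trial)
}

dx_row <- function(id = "P1", date, icd10 = "C32.0", setting = "inpatient",
                   primary_dx = TRUE) {
  data.frame(patient_id = id, date = as.Date(date), icd10 = icd10,
             setting = setting, primary_dx = primary_dx)
}

stage_row <- function(id = "P1", date, stage = "III") {
  data.frame(patient_id = id, date = as.Date(date), stage = stage)
}

drug_row <- function(id = "P1", date, agent = "cisplatin", atc = "L01XA01",
                     cost = 1000L) {
  data.frame(patient_id = id, date = as.Date(date), agent = agent, atc = atc,
             cost = as.integer(cost))
}

proc_row <- function(id = "P1", date, category, cost = 1000L) {
  data.frame(patient_id = id, date = as.Date(date), category = category,
             cost = as.integer(cost))
}

adm_row <- function(id = "P1", admit, discharge, cost = 100000L,
                    died = FALSE) {
  data.frame(patient_id = id, admit_date = as.Date(admit),
             discharge_date = as.Date(discharge), cost = as.integer(cost),
             died_in_hospital = died)
}

# claims for one (or more) patients with sensible defaults; event tables may
# be NULL
tiny_claims <- function(patients = patient_row(), diagnoses = NULL,
                        staging = NULL, drugs = NULL, procedures = NULL,
                        admissions = NULL, validate = TRUE) {
  claims_tables(patients = patients, diagnoses = diagnoses, staging = staging,
                drugs = drugs, procedures = procedures,
                admissions = admissions, validate = validate)
}

# a patient with a valid index at `index` (inpatient dx + stage claim)
indexed_claims <- function(index = "2018-03-01", stage = "III",
                           icd10 = "C32.0", drugs = NULL, procedures = NULL,
                           admissions = NULL, ...) {
  tiny_claims(
    patients = patient_row(...),
    diagnoses = dx_row(date = index, icd10 = icd10),
    staging = stage_row(date = index, stage = stage),
    drugs = drugs, procedures = procedures, admissions = admissions
  )
}

# one ICD-10 code per comorbidity category chosen to flag exactly that
# category (several categories share prefix neighbourhoods, e.g. I27.x)
eci_rep_codes <- c(
  congestive_heart_failure = "I50.0", cardiac_arrhythmias = "I47.0",
  valvular_disease = "I34.0", pulmonary_circulation = "I26.0",
  peripheral_vascular = "I70.0", hypertension = "I10.0",
  paralysis = "G81.0", other_neurological = "G20.0",
  chronic_pulmonary = "J44.9", diabetes_uncomplicated = "E11.9",
  diabetes_complicated = "E11.5", hypothyroidism = "E03.9",
  renal_failure = "N18.9", liver_disease = "K74.6", peptic_ulcer = "K25.7",
  aids_hiv = "B20.0", lymphoma = "C81.9", metastatic_cancer = "C78.0",
  solid_tumor = "C61.9", rheumatoid_arthritis = "M05.9",
  coagulopathy = "D68.9", obesity = "E66.0", weight_loss = "E43.9",
  fluid_electrolyte = "E86.9", blood_loss_anemia = "D50.0",
  deficiency_anemia = "D51.0", alcohol_abuse = "F10.2", drug_abuse = "F14.0",
  psychoses = "F22.0", depression = "F32.9"
)

run_pipeline <- function(claims, sel = selection_config(),
                         win = window_config()) {
  cohort <- select_cohort(claims, sel, win)
  eligible <- tidy(cohort)[cohort$eligible, , drop = FALSE]
  timelines <- derive_timelines(claims, eligible, win)
  labels <- classify_cohort(timelines)
  list(cohort = cohort, timelines = timelines, labels = labels)
}
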
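## Seeded synthetic claims generator.
##
## Emulates the structure of a Japanese hospital administrative claims
## database for the LA SCCHN analysis: per-patient event streams over
## 2015-2022 with head-and-neck diagnosis codes for four sites, TNM stage
## claims, treatment events realizing a configurable pathway mix, and
## resource-utilization / cost event processes. Pathways are realized
## constructively (gaps drawn inside the legal ranges of the sequencing
## rules), so the full pipeline recovers the intended label for every
## non-contaminant patient; a truth table records the intended verdicts for
## use as test ground truth.

pathway_labels <- c("surgery_alone", "surgery_then_crt", "surgery_then_rt",
                    "chemo_then_surgery", "other_resection", "crt",
                    "rt_alone", "chemo_then_rt", "rt_then_chemo",
                    "chemo_neck_dissection", "not_treated")

contaminant_kinds <- c("under_18", "prior_metastasis", "prior_other_stage",
                       "other_primary_cancer", "chemo_only", "clinical_trial",
                       "insufficient_pre_index")

# menus are named probability vectors keyed by "+"-joined component sets
parse_menu_key <- function(key) strsplit(key, "+", fixed = TRUE)[[1]]

default_regimen_menus <- function() {
  list(
    # systemic backbone of concurrent CRT
    crt_backbone = c(
      "cisplatin" = 1983, "cetuximab" = 257, "fluorouracil+cisplatin" = 128,
      "tegafur_gimeracil_oteracil" = 58,
      "fluorouracil+cisplatin+docetaxel" = 57, "carboplatin" = 47,
      "nedaplatin" = 28, "fluorouracil+carboplatin" = 25,
      "cisplatin+docetaxel" = 25, "other" = 47
    ) / 2655,
    # induction menus before surgery and before radiotherapy
    induction_pre_surgery = c(
      "fluorouracil+cisplatin" = 0.462,
      "fluorouracil+cisplatin+docetaxel" = 0.286,
      "cetuximab+paclitaxel+carboplatin" = 0.066, "other" = 0.186
    ),
    induction_pre_rt = c(
      "fluorouracil+cisplatin+docetaxel" = 0.556,
      "fluorouracil+cisplatin" = 0.254,
      "cetuximab+paclitaxel+carboplatin" = 0.082, "other" = 0.108
    ),
    # systemic component of adjuvant CRT after surgery
    adjuvant_crt = c(
      "cisplatin" = 331, "cetuximab" = 22, "fluorouracil+cisplatin" = 12,
      "tegafur_gimeracil_oteracil" = 12, "nedaplatin" = 8, "carboplatin" = 5,
      "fluorouracil+carboplatin" = 4, "fluorouracil+cisplatin+docetaxel" = 3,
      "cisplatin+docetaxel" = 1, "other" = 7
    ) / 405,
    post_rt_chemo = c("cisplatin" = 0.7, "fluorouracil+cisplatin" = 0.2,
                      "other" = 0.1),
    chemo_nd = c("cisplatin" = 0.8, "fluorouracil+cisplatin" = 0.2),
    late_chemo = c("cisplatin" = 0.7, "fluorouracil+cisplatin+docetaxel" = 0.1,
                   "fluorouracil+cisplatin" = 0.1, "other" = 0.1)
  )
}

# negative-binomial count processes (among users) and per-event log-normal
# costs, with the count ranges clipped to the observed min/max
default_hcru_rates <- function() {
  tibble(
    category = c("physician_visit", "admission", "prescription", "lab_test",
                 "imaging", "rehab_homecare"),
    user_prob = c(0.941, 0.998, 0.998, 0.991, 0.855, 0.551),
    mean = c(18.9, 2.2, 466.4, 37, 3.5, 22.3),
    size = c(2.6, 13.4, 1.3, 1.3, 13.5, 1.1),
    min = c(1, 1, 1, 1, 1, 1),
    max = c(119, 23, 5221, 347, 18, 241)
  )
}

default_cost_params <- function() {
  list(
    # per-event means (JPY); log-normal with sdlog 0.8
    event_mean = c(physician_visit = 18300, admission = 1641000,
                   prescription = 1358, lab_test = 2054, imaging = 1487,
                   rehab_homecare = 4155),
    sdlog = 0.8,
    # treatment events
    drug_admin_mean = 50000,
    surgery_cost = 800000,
    neck_dissection_cost = 500000,
    rt_fraction_cost = 30000
  )
}

default_comorbidity_menu <- function() {
  tibble(
    category = c("hypertension", "diabetes_uncomplicated", "chronic_pulmonary",
                 "cardiac_arrhythmias", "renal_failure",
                 "congestive_heart_failure", "valvular_disease", "depression",
                 "obesity", "fluid_electrolyte", "hypothyroidism",
                 "peptic_ulcer", "deficiency_anemia", "liver_disease",
                 "coagulopathy", "weight_loss", "alcohol_abuse", "psychoses"),
    icd10 = c("I10", "E11.9", "J44", "I48", "N18", "I50", "I35", "F32",
              "E66", "E87", "E03", "K25.9", "D50.9", "K74", "D68", "R64",
              "F10", "F20"),
    prob = c(0.30, 0.15, 0.25, 0.10, 0.04, 0.03, 0.05, 0.05, 0.02, 0.08,
             0.05, 0.05, 0.04, 0.01, 0.01, 0.05, 0.05, 0.01)
  )
}

#' Synthetic cohort generator configuration
#'
#' Defaults reproduce the study conditions of the source analysis: the
#' 2015-2022 claims calendar, the four-site and three-stage mixes, the
#' published treatment-pathway proportions, regimen menus per treatment
#' context, and resource-utilization count and cost processes of the
#' reported magnitudes. Contaminants are deliberately ineligible patients
#' that exercise every exclusion branch.
#'
#' @param n_patients number of patients to generate.
#' @param seed integer root seed; per-patient child seeds derive from it so
#'   cohorts are prefix-stable under changes of `n_patients`.
#' @param calendar_window observable claims period (Date pair).
#' @param diagnosis_window window for the index diagnosis (Date pair).
#' @param site_probs named probability vector over the four tumour sites.
#' @param stage_probs named probability vector over stages III/IVA/IVB.
#' @param pathway_probs named probability vector over the supported pathway
#'   labels (see `hncpatterns:::pathway_labels`).
#' @param regimen_menus per-context regimen probability vectors; names are
#'   `"+"`-joined component sets.
#' @param hcru_rates per-category count distributions (negative binomial
#'   among users, clipped to min/max).
#' @param cost_params per-event cost parameters (log-normal, JPY).
#' @param contaminant_probs named probabilities of the deliberately
#'   ineligible patient kinds; the remainder are clean patients.
#' @param comorbidity_menu per-category Bernoulli probabilities and
#'   representative ICD-10 codes for pre-index comorbidity claims.
#' @param hcru_enabled attach the resource-utilization stream (disable for
#'   pattern-only experiments; classification is invariant to it).
#' @param inpatient_dx_prob probability the index diagnosis is confirmed by
#'   an inpatient claim (otherwise two outpatient primary claims).
#' @param late_treatment_prob probability a not-treated patient starts
#'   systemic therapy after the 183-day treated window.
#' @return list of class `hnc_generator_config`.
#' @export
generator_config <- function(n_patients = 100,
                             seed = 1,
                             calendar_window = as.Date(c("2015-01-01",
                                                         "2022-07-31")),
                             diagnosis_window = as.Date(c("2016-01-01",
                                                          "2021-06-30")),
                             site_probs = c(oral_cavity = 1749, oropharynx = 1925,
                                            hypopharynx = 1721, larynx = 1346) / 6741,
                             stage_probs = c(III = 2266, IVA = 3577,
                                             IVB = 898) / 6741,
                             pathway_probs = c(
                               surgery_alone = 1422, surgery_then_crt = 405,
                               surgery_then_rt = 242, chemo_then_surgery = 91,
                               other_resection = 22, crt = 2655,
                               rt_alone = 437, chemo_then_rt = 331,
                               rt_then_chemo = 38, chemo_neck_dissection = 13,
                               not_treated = 1085) / 6741,
                             regimen_menus = default_regimen_menus(),
                             hcru_rates = default_hcru_rates(),
                             cost_params = default_cost_params(),
                             contaminant_probs = c(
                               under_18 = 0.02, prior_metastasis = 0.03,
                               prior_other_stage = 0.03,
                               other_primary_cancer = 0.03, chemo_only = 0.03,
                               clinical_trial = 0.03,
                               insufficient_pre_index = 0.03),
                             comorbidity_menu = default_comorbidity_menu(),
                             hcru_enabled = TRUE,
                             inpatient_dx_prob = 0.7,
                             late_treatment_prob = 0.022) {
  if (n_patients < 1) abort("`n_patients` must be positive")
  assert_prob_vector(site_probs, "site_probs")
  assert_prob_vector(stage_probs, "stage_probs")
  assert_prob_vector(pathway_probs, "pathway_probs")
  if (all(pathway_probs == 0)) abort("degenerate config: all-zero pathway_probs")
  stopifnot(all(names(pathway_probs) %in% pathway_labels))
  for (menu in regimen_menus) assert_prob_vector(menu, "regimen menu")
  if (any(contaminant_probs < 0) || sum(contaminant_probs) > 1) {
    abort("`contaminant_probs` must be non-negative and sum to at most 1")
  }
  structure(list(
    n_patients = n_patients, seed = seed,
    calendar_window = as.Date(calendar_window),
    diagnosis_window = as.Date(diagnosis_window),
    site_probs = site_probs, stage_probs = stage_probs,
    pathway_probs = pathway_probs, regimen_menus = regimen_menus,
    hcru_rates = hcru_rates, cost_params = cost_params,
    contaminant_probs = contaminant_probs,
    comorbidity_menu = comorbidity_menu,
    hcru_enabled = hcru_enabled,
    inpatient_dx_prob = inpatient_dx_prob,
    late_treatment_prob = late_treatment_prob
  ), class = "hnc_generator_config")
}

draw_one <- function(probs) sample(names(probs), 1, prob = probs)

rint <- function(lo, hi) sample(seq.int(lo, hi), 1)

lnorm_cost <- function(n, mean, sdlog = 0.8) {
  as.integer(round(rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)))
}

# one regimen course: each component administered on every cycle day; the
# non-anchor components start 0-2 days after the anchor (inside the 8-day
# combination window)
regimen_admins <- function(components, start_offset, n_cycles = NULL) {
  n_cycles <- n_cycles %||% rint(2, 3)
  cycle_days <- start_offset + 21 * (seq_len(n_cycles) - 1)
  offs <- c(0, sample(0:2, max(0, length(components) - 1), replace = TRUE))
  data.frame(
    offset = rep(cycle_days, times = length(components)) +
      rep(offs, each = n_cycles),
    agent = rep(components, each = n_cycles)
  )
}

rt_course_fractions <- function(start_offset, n_fractions = NULL) {
  n_fractions <- n_fractions %||% rint(28, 35)
  # weekday fractions: 5 on, 2 off
  day <- start_offset + (seq_len(n_fractions) - 1) %/% 5 * 7 +
    (seq_len(n_fractions) - 1) %% 5
  day
}

#' Realize a treatment pathway as dated events
#'
#' Emits the surgery, radiotherapy-fraction and drug-administration events
#' (as day offsets from the index date) that the requested pathway label
#' implies, drawing every gap strictly inside the legal range of the
#' sequencing rules so that episode derivation and classification recover
#' exactly the requested label (e.g. induction-to-radiotherapy gaps are
#' sequential, not concurrent; the CRT systemic anchor starts within 14
#' days of the radiotherapy course start).
#'
#' @param label one of the supported pathway labels.
#' @param regimen character vector of systemic components (ignored for
#'   surgery-/radiotherapy-only labels).
#' @param late_treatment emit post-window systemic therapy for
#'   `"not_treated"`.
#' @return list with data frames `drugs` (`offset`, `agent`),
#'   `procedures` (`offset`, `category`); offsets are days from index.
#' @export
realize_pathway <- function(label, regimen = "cisplatin",
                            late_treatment = FALSE) {
  if (!label %in% pathway_labels) {
    abort(sprintf("unsupported pathway label: %s", label))
  }
  drugs <- data.frame(offset = integer(0), agent = character(0))
  procedures <- data.frame(offset = integer(0), category = character(0))
  add_proc <- function(offset, category) {
    procedures <<- rbind(procedures, data.frame(offset = offset,
                                                category = category))
  }
  if (label == "surgery_alone") {
    add_proc(rint(5, 40), "surgery_resection")
  } else if (label == "surgery_then_rt") {
    s0 <- rint(5, 30)
    add_proc(s0, "surgery_resection")
    add_proc(rt_course_fractions(s0 + rint(20, 60)), "radiotherapy_fraction")
  } else if (label == "surgery_then_crt") {
    s0 <- rint(5, 30)
    add_proc(s0, "surgery_resection")
    r0 <- s0 + rint(20, 60)
    add_proc(rt_course_fractions(r0), "radiotherapy_fraction")
    drugs <- regimen_admins(regimen, r0 + rint(0, 7))
  } else if (label == "chemo_then_surgery") {
    c0 <- rint(5, 20)
    drugs <- regimen_admins(regimen, c0)
    add_proc(c0 + rint(50, 80), "surgery_resection")
  } else if (label == "other_resection") {
    # a three-modality surgical sequence: surgery -> chemo -> radiotherapy,
    # chemo and radiotherapy sequential (outside the 14-day pairing window)
    s0 <- rint(5, 20)
    add_proc(s0, "surgery_resection")
    c0 <- s0 + rint(15, 28)
    drugs <- regimen_admins(regimen, c0, n_cycles = 2)
    add_proc(rt_course_fractions(c0 + rint(20, 40), n_fractions = rint(20, 30)),
             "radiotherapy_fraction")
  } else if (label == "crt") {
    r0 <- rint(10, 50)
    add_proc(rt_course_fractions(r0), "radiotherapy_fraction")
    drugs <- regimen_admins(regimen, r0 + rint(0, 10), n_cycles = 3)
  } else if (label == "rt_alone") {
    add_proc(rt_course_fractions(rint(10, 60)), "radiotherapy_fraction")
  } else if (label == "chemo_then_rt") {
    c0 <- rint(5, 20)
    drugs <- regimen_admins(regimen, c0)
    add_proc(rt_course_fractions(c0 + rint(48, 80)), "radiotherapy_fraction")
  } else if (label == "rt_then_chemo") {
    r0 <- rint(5, 30)
    add_proc(rt_course_fractions(r0), "radiotherapy_fraction")
    drugs <- regimen_admins(regimen, r0 + rint(15, 60))
  } else if (label == "chemo_neck_dissection") {
    c0 <- rint(5, 30)
    drugs <- regimen_admins(regimen, c0)
    add_proc(c0 + rint(20, 60), "neck_dissection")
  } else if (label == "not_treated") {
    if (late_treatment) drugs <- regimen_admins(regimen, rint(190, 280))
  }
  list(drugs = drugs, procedures = procedures)
}

hnc_site_code <- function(site) {
  prefix <- sample(hnc_code_prefixes[[site]], 1)
  paste0(prefix, ".", sample(0:9, 1))
}

# resource events for one patient in the first post-index year
hcru_events_one <- function(window_days, rates, costs) {
  out <- list(procedures = NULL, drugs = NULL, admissions = NULL)
  counts <- integer(nrow(rates))
  for (j in seq_len(nrow(rates))) {
    if (runif(1) > rates$user_prob[j]) next
    k <- rnbinom(1, size = rates$size[j], mu = rates$mean[j])
    counts[j] <- min(max(k, rates$min[j]), rates$max[j])
  }
  names(counts) <- rates$category
  draw_days <- function(k) sort(sample.int(window_days, k, replace = TRUE)) - 1L
  proc_cats <- c("physician_visit", "lab_test", "imaging", "rehab_homecare")
  po <- integer(0); pc <- character(0); pcost <- integer(0)
  for (cat in proc_cats) {
    k <- counts[[cat]]
    if (k == 0) next
    po <- c(po, draw_days(k))
    pc <- c(pc, rep(cat, k))
    pcost <- c(pcost, lnorm_cost(k, costs$event_mean[[cat]], costs$sdlog))
  }
  out$procedures <- data.frame(offset = po, category = pc, cost = pcost)
  k <- counts[["prescription"]]
  if (k > 0) {
    out$drugs <- data.frame(
      offset = draw_days(k), agent = "other", atc = "N02BE01",
      cost = lnorm_cost(k, costs$event_mean[["prescription"]], costs$sdlog)
    )
  }
  k <- counts[["admission"]]
  if (k > 0) {
    admit <- draw_days(k)
    out$admissions <- data.frame(
      offset = admit,
      los = sample(3:20, k, replace = TRUE),
      cost = lnorm_cost(k, costs$event_mean[["admission"]], costs$sdlog)
    )
  }
  out
}

#' Generate a synthetic claims cohort with ground truth
#'
#' Produces exactly `n_patients` patients: clean patients realize a pathway
#' drawn from `pathway_probs` with all sequencing constraints satisfied;
#' contaminant patients carry one deliberate eligibility defect each. A
#' truth table records, per patient, the intended eligibility verdict,
#' pathway label, site, stage and regimen. The same configuration (and
#' seed) always reproduces the identical cohort.
#'
#' @param config a [generator_config()].
#' @return list with `claims` (an `hnc_claims`) and `truth` (a tibble).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "hnc_generator_config"))
  n <- config$n_patients
  set.seed(config$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1, n, replace = TRUE)

  acc <- list(patients = vector("list", n), diagnoses = vector("list", n),
              staging = vector("list", n), drugs = vector("list", n),
              procedures = vector("list", n), admissions = vector("list", n))
  truth <- vector("list", n)
  data_end <- config$calendar_window[2]
  kinds <- c(none = 1 - sum(config$contaminant_probs), config$contaminant_probs)

  for (i in seq_len(n)) {
    set.seed(child_seeds[i])
    id <- sprintf("P%06d", i)
    contaminant <- draw_one(kinds)
    site <- draw_one(config$site_probs)
    stage <- draw_one(config$stage_probs)
    pathway <- draw_one(config$pathway_probs)
    if (contaminant == "chemo_only") pathway <- "chemo_only"
    sex <- if (runif(1) < 0.809) "male" else "female"
    index <- config$diagnosis_window[1] +
      rint(0, days_between(config$diagnosis_window[1], config$diagnosis_window[2]))
    age <- if (contaminant == "under_18") rint(15, 17) else
      min(max(round(rnorm(1, 67.7, 11.8)), 20), 99)
    birth_year <- as.integer(format(index, "%Y")) - age
    pre_span <- if (contaminant == "insufficient_pre_index") rint(100, 300) else
      rint(365, 730)

    # treatment events
    menu_key <- switch(pathway,
      crt = "crt_backbone", surgery_then_crt = "adjuvant_crt",
      chemo_then_surgery = "induction_pre_surgery",
      chemo_then_rt = "induction_pre_rt", rt_then_chemo = "post_rt_chemo",
      chemo_neck_dissection = "chemo_nd", not_treated = "late_chemo",
      other_resection = "crt_backbone", chemo_only = "chemo_nd", NULL)
    regimen <- if (is.null(menu_key)) character(0) else
      parse_menu_key(draw_one(config$regimen_menus[[menu_key]]))
    late <- pathway == "not_treated" && runif(1) < config$late_treatment_prob
    ev <- if (pathway == "chemo_only") {
      list(drugs = regimen_admins(regimen, rint(5, 30)),
           procedures = data.frame(offset = integer(0), category = character(0)))
    } else {
      realize_pathway(pathway, regimen, late_treatment = late)
    }

    last_event <- max(c(ev$drugs$offset, ev$procedures$offset, 0))
    fu_draw <- round(rlnorm(1, log(650), 0.9))
    fu <- min(max(fu_draw, last_event + 5, 30), days_between(index, data_end))
    enroll_start <- index - pre_span
    enroll_end <- index + fu

    # diagnosis and staging claims
    code <- hnc_site_code(site)
    if (runif(1) < config$inpatient_dx_prob) {
      dx <- data.frame(date = index, icd10 = code, setting = "inpatient",
                       primary_dx = TRUE)
    } else {
      dx <- data.frame(date = c(index, index + rint(7, min(30, fu))),
                       icd10 = code, setting = "outpatient", primary_dx = TRUE)
    }
    st <- data.frame(date = index + rint(0, min(45, fu)), stage = stage)

    # pre-index comorbidity claims
    menu <- config$comorbidity_menu
    flag <- runif(nrow(menu)) < menu$prob
    if (any(flag)) {
      dx <- rbind(dx, data.frame(
        date = index - sample(seq.int(30, min(360, pre_span - 5)), sum(flag),
                              replace = TRUE),
        icd10 = menu$icd10[flag], setting = "outpatient", primary_dx = FALSE))
    }

    # contaminant defects
    trial <- FALSE
    expected_reason <- NA_character_
    if (contaminant == "under_18") expected_reason <- "age"
    if (contaminant == "prior_metastasis") {
      dx <- rbind(dx, data.frame(
        date = index - rint(30, min(300, pre_span - 5)),
        icd10 = paste0(sample(c("C78", "C79"), 1), ".", sample(0:9, 1)),
        setting = "outpatient", primary_dx = FALSE))
      expected_reason <- "prior_metastasis"
    }
    if (contaminant == "prior_other_stage") {
      st <- rbind(st, data.frame(
        date = index - rint(30, min(300, pre_span - 5)),
        stage = sample(c("I", "II", "IVC"), 1)))
      expected_reason <- "prior_other_stage"
    }
    if (contaminant == "other_primary_cancer") {
      dx <- rbind(dx, data.frame(
        date = index - rint(30, min(300, pre_span - 5)),
        icd10 = sample(c("C16.9", "C18.9", "C34.9", "C61"), 1),
        setting = "outpatient", primary_dx = FALSE))
      expected_reason <- "other_primary_cancer"
    }
    if (contaminant == "chemo_only") expected_reason <- "chemo_only"
    if (contaminant == "clinical_trial") {
      trial <- TRUE
      expected_reason <- "clinical_trial"
    }
    if (contaminant == "insufficient_pre_index") {
      expected_reason <- "insufficient_pre_index"
    }

    # treatment event rows with costs
    costs <- config$cost_params
    drg <- NULL
    if (nrow(ev$drugs) > 0) {
      drg <- data.frame(
        date = index + ev$drugs$offset, agent = ev$drugs$agent,
        atc = "L01XA01",
        cost = lnorm_cost(nrow(ev$drugs), costs$drug_admin_mean, costs$sdlog))
    }
    prc <- NULL
    if (nrow(ev$procedures) > 0) {
      pcost <- ifelse(ev$procedures$category == "surgery_resection",
                      costs$surgery_cost,
               ifelse(ev$procedures$category == "neck_dissection",
                      costs$neck_dissection_cost, costs$rt_fraction_cost))
      prc <- data.frame(date = index + ev$procedures$offset,
                        category = ev$procedures$category,
                        cost = as.integer(pcost))
    }
    adm <- NULL
    if (config$hcru_enabled) {
      h <- hcru_events_one(min(365, fu), config$hcru_rates, costs)
      if (!is.null(h$procedures) && nrow(h$procedures) > 0) {
        prc <- rbind(prc, data.frame(date = index + h$procedures$offset,
                                     category = h$procedures$category,
                                     cost = h$procedures$cost))
      }
      if (!is.null(h$drugs) && nrow(h$drugs) > 0) {
        drg <- rbind(drg, data.frame(date = index + h$drugs$offset,
                                     agent = h$drugs$agent, atc = h$drugs$atc,
                                     cost = h$drugs$cost))
      }
      if (!is.null(h$admissions) && nrow(h$admissions) > 0) {
        admit <- index + h$admissions$offset
        adm <- data.frame(
          admit_date = admit,
          discharge_date = pmin(admit + h$admissions$los, enroll_end),
          cost = h$admissions$cost, died_in_hospital = FALSE)
      }
    }
    if (is.null(drg)) {
      drg <- data.frame(date = as.Date(character(0)), agent = character(0),
                        atc = character(0), cost = integer(0))
    } else if (!"atc" %in% names(drg)) {
      drg$atc <- "L01XA01"
    }

    acc$patients[[i]] <- data.frame(
      patient_id = id, birth_year = birth_year, sex = sex,
      enroll_start = enroll_start, enroll_end = enroll_end,
      death_date = as.Date(NA), clinical_trial = trial)
    acc$diagnoses[[i]] <- data.frame(patient_id = id, dx)
    acc$staging[[i]] <- data.frame(patient_id = id, st)
    if (nrow(drg) > 0) acc$drugs[[i]] <- data.frame(patient_id = id, drg)
    if (!is.null(prc)) acc$procedures[[i]] <- data.frame(patient_id = id, prc)
    if (!is.null(adm)) acc$admissions[[i]] <- data.frame(patient_id = id, adm)

    truth[[i]] <- data.frame(
      patient_id = id, contaminant = contaminant,
      eligible = is.na(expected_reason),
      exclusion_reason = expected_reason,
      pathway = if (pathway == "chemo_only") "chemo_only" else pathway,
      site = site, stage = stage,
      regimen = if (length(regimen) > 0) regimen_name(regimen) else NA_character_,
      index_date = index, follow_up_days = fu)
  }

  bind_or_null <- function(lst) {
    out <- dplyr::bind_rows(lst)
    if (nrow(out) == 0) NULL else out
  }
  claims <- claims_tables(
    patients = bind_or_null(acc$patients),
    diagnoses = bind_or_null(acc$diagnoses),
    staging = bind_or_null(acc$staging),
    drugs = bind_or_null(acc$drugs),
    procedures = bind_or_null(acc$procedures),
    admissions = bind_or_null(acc$admissions),
    validate = FALSE
  )
  list(claims = claims, truth = tibble::as_tibble(dplyr::bind_rows(truth)))
}

#' Attach a resource-utilization stream to existing claims
#'
#' Adds physician-visit, laboratory, imaging, rehabilitation, prescription
#' and admission events (with log-normal costs) over each patient's first
#' post-index year, leaving treatment events untouched. Classification is
#' invariant to these events.
#'
#' @param claims an `hnc_claims` object.
#' @param index_dates tibble with `patient_id`, `index_date`.
#' @param hcru_rates count distributions, as in [generator_config()].
#' @param cost_params cost parameters, as in [generator_config()].
#' @param seed integer seed.
#' @return the augmented `hnc_claims`.
#' @export
attach_hcru_stream <- function(claims, index_dates,
                               hcru_rates = default_hcru_rates(),
                               cost_params = default_cost_params(),
                               seed = 1) {
  stopifnot(inherits(claims, "hnc_claims"))
  set.seed(seed)
  pts <- claims$patients
  new_proc <- list(); new_drug <- list(); new_adm <- list()
  for (i in seq_len(nrow(index_dates))) {
    id <- index_dates$patient_id[i]
    index <- index_dates$index_date[i]
    j <- match(id, pts$patient_id)
    if (is.na(j) || is.na(index)) next
    fu <- days_between(index, pts$enroll_end[j])
    if (fu < 1) next
    h <- hcru_events_one(min(365, fu), hcru_rates, cost_params)
    if (!is.null(h$procedures) && nrow(h$procedures) > 0) {
      new_proc[[length(new_proc) + 1]] <- data.frame(
        patient_id = id, date = index + h$procedures$offset,
        category = h$procedures$category, cost = h$procedures$cost)
    }
    if (!is.null(h$drugs) && nrow(h$drugs) > 0) {
      new_drug[[length(new_drug) + 1]] <- data.frame(
        patient_id = id, date = index + h$drugs$offset, agent = h$drugs$agent,
        atc = h$drugs$atc, cost = h$drugs$cost)
    }
    if (!is.null(h$admissions) && nrow(h$admissions) > 0) {
      admit <- index + h$admissions$offset
      new_adm[[length(new_adm) + 1]] <- data.frame(
        patient_id = id, admit_date = admit,
        discharge_date = pmin(admit + h$admissions$los, pts$enroll_end[j]),
        cost = h$admissions$cost, died_in_hospital = FALSE)
    }
  }
  claims_tables(
    patients = claims$patients,
    diagnoses = claims$diagnoses,
    staging = claims$staging,
    drugs = dplyr::bind_rows(c(list(claims$drugs), new_drug)),
    procedures = dplyr::bind_rows(c(list(claims$procedures), new_proc)),
    admissions = dplyr::bind_rows(c(list(claims$admissions), new_adm)),
    validate = FALSE
  )
}
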
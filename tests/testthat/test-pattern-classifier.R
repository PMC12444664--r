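origin <- as.Date("2018-01-01")

mk_timeline <- function(surgery = integer(0), rt = integer(0),
                        drugs = NULL, nd = integer(0), obs_end = 400) {
  drugs <- drugs %||% tibble::tibble(date = as.Date(character(0)),
                                     agent = character(0))
  derive_timeline(
    surgeries = origin + surgery, rt_fractions = origin + rt,
    drugs = drugs, index_date = origin, observation_end = origin + obs_end,
    neck_dissections = origin + nd
  )
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("hand-built timelines map to the expected taxonomy labels", {
  lab <- classify_timeline(mk_timeline(surgery = 10))
  expect_equal(lab$top, "primary_resection")
  expect_equal(lab$sub, "surgery_alone")

  crt_after_surgery <- mk_timeline(
    surgery = 10, rt = 40:74,
    drugs = tibble::tibble(date = origin + c(42, 63, 84), agent = "cisplatin"))
  lab <- classify_timeline(crt_after_surgery)
  expect_equal(lab$sub, "surgery_then_crt")

  induction_then_rt <- mk_timeline(
    rt = 35:65,
    drugs = tibble::tibble(date = origin + c(0, 1, 1),
                           agent = c("docetaxel", "cisplatin", "fluorouracil")))
  lab <- classify_timeline(induction_then_rt)
  expect_equal(lab$top, "definitive_nonsurgical")
  expect_equal(lab$sub, "chemo_then_rt")

  rt_only <- classify_timeline(mk_timeline(rt = 10:44))
  expect_equal(rt_only$sub, "rt_alone")

  crt <- classify_timeline(mk_timeline(
    rt = 10:44,
    drugs = tibble::tibble(date = origin + c(12, 33, 54), agent = "cisplatin")))
  expect_equal(crt$sub, "crt_alone")

  rt_then_chemo <- classify_timeline(mk_timeline(
    rt = 5:35,
    drugs = tibble::tibble(date = origin + c(50, 71), agent = "cisplatin")))
  expect_equal(rt_then_chemo$sub, "rt_then_chemo")

  untreated <- classify_timeline(mk_timeline())
  expect_equal(untreated$top, "not_treated")
  expect_equal(untreated$sub, "none")

  chemo_nd <- classify_timeline(mk_timeline(
    drugs = tibble::tibble(date = origin + c(5, 26), agent = "cisplatin"),
    nd = 40))
  expect_equal(chemo_nd$top, "chemo_neck_dissection")

  three_modality <- mk_timeline(
    surgery = 5,
    drugs = tibble::tibble(date = origin + c(25, 46), agent = "cisplatin"),
    rt = 50:80)
  lab <- classify_timeline(three_modality)
  expect_equal(lab$sub, "other_resection")
})

test_that("pattern tables reproduce printed percentages and partition the cohort", {
  labels <- tibble::tibble(
    patient_id = sprintf("P%04d", 1:20),
    top = factor(rep(c("definitive_nonsurgical", "primary_resection",
                       "not_treated", "chemo_neck_dissection"),
                     c(10, 6, 3, 1)),
                 levels = hncpatterns:::pattern_tops),
    sub = factor("none", levels = hncpatterns:::pattern_subs),
    sequence = ""
  )
  tab <- tabulate_patterns(labels)
  expect_equal(sum(tab$n), 20)
  expect_equal(tab$pct[match("definitive_nonsurgical", tab$label)], 50.0)
  expect_equal(tab$cell[match("primary_resection", tab$label)], "6 (30.0)")

  single <- tabulate_patterns(labels[1, ])
  expect_equal(single$pct[match("definitive_nonsurgical", single$label)], 100.0)
})

test_that("per-stratum cells always sum to the stratum N", {
  set.seed(31)
  sim <- generate_cohort(generator_config(n_patients = 150, seed = 31,
                                          hcru_enabled = FALSE))
  res <- run_pipeline(sim$claims)
  cohort <- tidy(res$cohort)[res$cohort$eligible, ]
  for (by in c("site", "stage", "age")) {
    tab <- tabulate_patterns(res$labels, cohort, by = by)
    sums <- tapply(tab$n, tab$stratum, sum)
    expected <- table(switch(by, site = cohort$site, stage = cohort$stage,
                             age = cohort$age_band))
    expected <- expected[expected > 0]
    expect_equal(as.integer(sums[names(expected)]), as.integer(expected))
  }
  # exhaustive partition: top-level counts sum to cohort N
  overall <- tabulate_patterns(res$labels)
  expect_equal(sum(overall$n), nrow(cohort))
})

test_that("generator-to-classifier closure holds for every pathway label", {
  set.seed(62)
  labels <- setdiff(hncpatterns:::pathway_labels, "not_treated")
  expected <- c(surgery_alone = "surgery_alone",
                surgery_then_crt = "surgery_then_crt",
                surgery_then_rt = "surgery_then_rt",
                chemo_then_surgery = "chemo_then_surgery",
                other_resection = "other_resection", crt = "crt_alone",
                rt_alone = "rt_alone", chemo_then_rt = "chemo_then_rt",
                rt_then_chemo = "rt_then_chemo",
                chemo_neck_dissection = "none")
  for (label in labels) {
    for (rep in 1:25) {
      ev <- realize_pathway(label, regimen = c("cisplatin", "fluorouracil"))
      tl <- derive_timeline(
        surgeries = origin + ev$procedures$offset[
          ev$procedures$category == "surgery_resection"],
        rt_fractions = origin + ev$procedures$offset[
          ev$procedures$category == "radiotherapy_fraction"],
        drugs = tibble::tibble(date = origin + ev$drugs$offset,
                               agent = ev$drugs$agent),
        index_date = origin, observation_end = origin + 500,
        neck_dissections = origin + ev$procedures$offset[
          ev$procedures$category == "neck_dissection"]
      )
      lab <- classify_timeline(tl)
      expect_equal(lab$sub, unname(expected[label]),
                   label = sprintf("sub for pathway %s (rep %d)", label, rep))
    }
  }
  expect_equal(classify_timeline(mk_timeline())$top, "not_treated")
})

test_that("classification ignores resource-utilization events", {
  sim <- generate_cohort(generator_config(n_patients = 80, seed = 9,
                                          hcru_enabled = FALSE))
  res <- run_pipeline(sim$claims)
  eligible <- tidy(res$cohort)[res$cohort$eligible, c("patient_id", "index_date")]
  with_hcru <- attach_hcru_stream(sim$claims, eligible, seed = 4)
  res2 <- run_pipeline(with_hcru)
  both <- dplyr::inner_join(res$labels, res2$labels, by = "patient_id")
  expect_equal(as.character(both$sub.x), as.character(both$sub.y))
  expect_equal(as.character(both$top.x), as.character(both$top.y))
})

test_that("regimen frequencies are canonical names summing to the subgroup N", {
  set.seed(12)
  cfg <- generator_config(
    n_patients = 120, seed = 12, hcru_enabled = FALSE,
    contaminant_probs = c(under_18 = 0),
    pathway_probs = c(chemo_then_rt = 1)
  )
  sim <- generate_cohort(cfg)
  res <- run_pipeline(sim$claims)
  dist <- regimen_distribution(res$timelines, res$labels, "induction_pre_rt")
  expect_equal(sum(dist$n), nrow(res$labels))
  expect_true(all(dist$regimen %in% c(
    "fluorouracil + cisplatin + docetaxel", "fluorouracil + cisplatin",
    "cetuximab + paclitaxel + carboplatin", "other")))
  empty <- regimen_distribution(res$timelines, res$labels, "adjuvant_crt")
  expect_equal(nrow(empty), 0L)
})

test_that("canonical regimen naming follows the display precedence", {
  expect_equal(regimen_name(c("docetaxel", "cisplatin", "fluorouracil")),
               "fluorouracil + cisplatin + docetaxel")
  expect_equal(regimen_name(c("carboplatin", "paclitaxel", "cetuximab")),
               "cetuximab + paclitaxel + carboplatin")
  expect_equal(regimen_name(c("cisplatin", "cisplatin")), "cisplatin")
  expect_true(is.na(regimen_name(character(0))))
})
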
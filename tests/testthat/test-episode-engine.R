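origin <- as.Date("2018-01-01")

test_that("radiotherapy fractions merge into courses by the 14-day gap rule", {
  daily33 <- build_rt_courses(origin + 0:32)
  expect_equal(nrow(daily33), 1L)
  expect_equal(daily33$fraction_count, 33L)

  split_course <- build_rt_courses(origin + c(0:20, 40:60))
  expect_equal(nrow(split_course), 2L)
  expect_equal(as.integer(split_course$start - origin), c(0L, 40L))

  single <- build_rt_courses(origin)
  expect_equal(single$start, single$end)
  expect_equal(single$fraction_count, 1L)
})

test_that("agents starting within 8 days of the anchor join the regimen", {
  tpf <- build_systemic_regimens(tibble::tibble(
    date = origin + c(0, 1, 1),
    agent = c("docetaxel", "cisplatin", "fluorouracil")
  ))
  expect_equal(nrow(tpf), 1L)
  expect_setequal(tpf$components[[1]],
                  c("docetaxel", "cisplatin", "fluorouracil"))

  late_add <- build_systemic_regimens(tibble::tibble(
    date = origin + c(0, 20), agent = c("cisplatin", "cetuximab")
  ))
  expect_equal(nrow(late_add), 2L)
  expect_equal(late_add$components[[1]], "cisplatin")
  expect_equal(late_add$components[[2]], "cetuximab")
})

test_that("cycles within 60-day lapses form one block; longer lapses split", {
  cycles <- build_systemic_regimens(tibble::tibble(
    date = origin + c(0, 21, 42), agent = "cisplatin"))
  expect_equal(nrow(cycles), 1L)
  expect_equal(as.integer(cycles$end - origin), 42L)

  lapsed <- build_systemic_regimens(tibble::tibble(
    date = origin + c(0, 70), agent = "cisplatin"))
  expect_equal(nrow(lapsed), 2L)
})

test_that("CRT pairing is sharp at the 14-day start-gap boundary", {
  mk <- function(sys_day) {
    blocks <- tibble::tibble(
      modality = c("radiotherapy", "systemic"),
      start = origin + c(30, sys_day), end = origin + c(70, sys_day + 42),
      components = list("rt_course", "cisplatin")
    )
    pair_concurrent_crt(blocks)
  }
  expect_equal(mk(30)$pair, c(2L, 1L))
  expect_equal(mk(44)$pair, c(2L, 1L))   # 14 days: inside
  expect_true(all(is.na(mk(45)$pair)))   # 15 days: outside
})

test_that("widening the concurrency window never un-pairs a paired CRT", {
  set.seed(77)
  for (rep in 1:30) {
    blocks <- tibble::tibble(
      modality = c("radiotherapy", "systemic", "systemic"),
      start = origin + sample(0:60, 3),
      end = origin + sample(61:120, 3),
      components = list("rt_course", "cisplatin", "cetuximab")
    )
    narrow <- pair_concurrent_crt(blocks, window_config(concurrent_window_days = 7))
    wide <- pair_concurrent_crt(blocks, window_config(concurrent_window_days = 21))
    paired_narrow <- which(!is.na(narrow$pair))
    expect_true(all(paired_narrow %in% which(!is.na(wide$pair))))
  }
})

test_that("the LA treatment covers blocks starting within 90 days of the first", {
  tl <- derive_timeline(
    surgeries = origin + 10,
    rt_fractions = origin + 55:85,
    drugs = tibble::tibble(date = as.Date(character(0)), agent = character(0)),
    index_date = origin, observation_end = origin + 400
  )
  expect_true(tl$treated)
  expect_equal(nrow(tl$blocks), 2L)
  expect_equal(nrow(tl$after), 0L)
})

test_that("treatment starting after 183 days leaves the patient untreated", {
  tl <- derive_timeline(
    surgeries = as.Date(character(0)), rt_fractions = as.Date(character(0)),
    drugs = tibble::tibble(date = origin + 200, agent = "cisplatin"),
    index_date = origin, observation_end = origin + 400
  )
  expect_false(tl$treated)
  expect_equal(nrow(tl$blocks), 0L)
  expect_equal(nrow(tl$after), 1L)

  empty <- derive_timeline(
    surgeries = as.Date(character(0)), rt_fractions = as.Date(character(0)),
    drugs = tibble::tibble(date = as.Date(character(0)), agent = character(0)),
    index_date = origin, observation_end = origin + 400
  )
  expect_false(empty$treated)
  expect_equal(nrow(empty$blocks), 0L)
})

test_that("switch and discontinuation follow the 8/60-day rules", {
  mk <- function(successor_day, successor_agent = "cetuximab") {
    derive_timeline(
      surgeries = as.Date(character(0)), rt_fractions = as.Date(character(0)),
      drugs = tibble::tibble(
        date = origin + c(0, 50, 100, successor_day),
        agent = c(rep("cisplatin", 3), successor_agent)),
      index_date = origin, observation_end = origin + 500
    )
  }
  expect_equal(mk(130)$line_end, "switched")      # 30 days after end
  expect_equal(mk(170)$line_end, "discontinued")  # 70 days after end

  # combination switch: {cisplatin + fluorouracil} ends day 42; a new
  # combination {nedaplatin + docetaxel} starts day 95 (53 days after the
  # end, past the 90-day LA window) and persists 15 days
  combo <- derive_timeline(
    surgeries = as.Date(character(0)), rt_fractions = as.Date(character(0)),
    drugs = tibble::tibble(
      date = origin + c(0, 1, 21, 42, 95, 96, 110, 110),
      agent = c("cisplatin", "fluorouracil", "cisplatin", "fluorouracil",
                "nedaplatin", "docetaxel", "nedaplatin", "docetaxel")),
    index_date = origin, observation_end = origin + 500
  )
  expect_equal(combo$line_end, "switched")
})

test_that("window boundaries fall on the correct side for every rule", {
  # 8-day combination window
  b8 <- build_systemic_regimens(tibble::tibble(
    date = origin + c(0, 8), agent = c("cisplatin", "fluorouracil")))
  b9 <- build_systemic_regimens(tibble::tibble(
    date = origin + c(0, 9), agent = c("cisplatin", "fluorouracil")))
  expect_equal(nrow(b8), 1L)
  expect_equal(nrow(b9), 2L)
  # 60-day prescription gap
  g60 <- build_systemic_regimens(tibble::tibble(
    date = origin + c(0, 60), agent = "cisplatin"))
  g61 <- build_systemic_regimens(tibble::tibble(
    date = origin + c(0, 61), agent = "cisplatin"))
  expect_equal(nrow(g60), 1L)
  expect_equal(nrow(g61), 2L)
  # 90-day modality window
  mk90 <- function(d) derive_timeline(
    surgeries = origin + c(0, d), rt_fractions = as.Date(character(0)),
    drugs = tibble::tibble(date = as.Date(character(0)), agent = character(0)),
    index_date = origin, observation_end = origin + 400)
  expect_equal(nrow(mk90(90)$blocks), 2L)
  expect_equal(nrow(mk90(91)$blocks), 1L)
  # 183-day treated window
  mk183 <- function(d) derive_timeline(
    surgeries = origin + d, rt_fractions = as.Date(character(0)),
    drugs = tibble::tibble(date = as.Date(character(0)), agent = character(0)),
    index_date = origin, observation_end = origin + 400)
  expect_true(mk183(183)$treated)
  expect_false(mk183(184)$treated)
  # 14-day concurrency window covered in the pairing test above
})

test_that("the engine matches the brute-force day scanner on random event sets", {
  set.seed(1234)
  cfg <- window_config()
  for (rep in 1:300) {
    ev <- random_event_set()
    tl <- engine_timeline_from_days(ev, cfg)
    or <- oracle_timeline(ev$surgery, ev$rt, ev$drugs, ev$obs_end, cfg)
    expect_equal(tl$treated, or$treated)
    if (or$treated) {
      day0 <- as.integer(origin)
      expect_equal(engine_signatures(tl$blocks, day0), oracle_signatures(or$la))
      expect_equal(engine_signatures(tl$after, day0), oracle_signatures(or$after))
      expect_equal(engine_pair_signatures(tl$blocks, day0),
                   oracle_pair_signatures(Filter(function(p) {
                     any(sapply(or$la, function(b)
                       b$modality == "systemic" && b$start == p[["sys"]]))
                   }, or$pairs)))
      expect_equal(tl$line_end, or$line_end)
    }
  }
})

test_that("shuffling claim rows never changes the derived timeline", {
  set.seed(555)
  for (rep in 1:20) {
    ev <- random_event_set()
    tl1 <- engine_timeline_from_days(ev)
    ev$drugs <- ev$drugs[sample.int(nrow(ev$drugs)), , drop = FALSE]
    ev$rt <- ev$rt[sample.int(length(ev$rt))]
    ev$surgery <- ev$surgery[sample.int(length(ev$surgery))]
    tl2 <- engine_timeline_from_days(ev)
    expect_equal(engine_signatures(tl1$blocks, 0L), engine_signatures(tl2$blocks, 0L))
    expect_equal(tl1$line_end, tl2$line_end)
  }
})
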
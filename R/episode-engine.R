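## Temporal treatment-sequencing engine.
##
## Raw dated claims are folded into modality-level blocks:
##   * radiotherapy fractions merge into courses when inter-fraction gaps
##     stay within `rt_course_merge_gap_days`;
##   * drug administrations form regimen blocks: agents whose first
##     administration falls within `combo_window_days` (8) of the anchor
##     agent join the combination, a lapse of more than `gap_days` (60)
##     ends the block;
##   * a systemic block and a radiotherapy course starting within
##     `concurrent_window_days` (14) of each other are paired as concurrent
##     chemoradiotherapy (CRT);
##   * the locally advanced (LA) treatment covers blocks starting within
##     `modality_window_days` (90) of the first treatment, provided that
##     first treatment began within `treated_window_days` (183) of the
##     index date;
##   * the line ends by a switch (qualifying successor within 60 days of
##     the current end) or a discontinuation (more than 60 treatment-free
##     days); add-ons neither end nor advance the line.

#' Window constants for episode derivation
#'
#' All windows are inclusive whole-day differences; 6 months is fixed at 183
#' days and 12 months at 365 days.
#'
#' @param treated_window_days max days from index to first treatment for a
#'   patient to count as treated.
#' @param modality_window_days window after the first treatment start within
#'   which blocks belong to the LA treatment.
#' @param combo_window_days window after the first systemic agent within
#'   which additional agents join the combination.
#' @param concurrent_window_days max start-date gap for a systemic block and
#'   a radiotherapy course to count as concurrent CRT.
#' @param gap_days treatment-free gap that ends a block / defines
#'   discontinuation.
#' @param rt_course_merge_gap_days max inter-fraction gap within one
#'   radiotherapy course.
#' @return a list of window constants, class `hnc_window_config`.
#' @export
window_config <- function(treated_window_days = 183,
                          modality_window_days = 90,
                          combo_window_days = 8,
                          concurrent_window_days = 14,
                          gap_days = 60,
                          rt_course_merge_gap_days = 14) {
  cfg <- list(
    treated_window_days = treated_window_days,
    modality_window_days = modality_window_days,
    combo_window_days = combo_window_days,
    concurrent_window_days = concurrent_window_days,
    gap_days = gap_days,
    rt_course_merge_gap_days = rt_course_merge_gap_days
  )
  if (any(unlist(cfg) <= 0)) abort("all window constants must be positive")
  structure(cfg, class = "hnc_window_config")
}

#' Merge radiotherapy fraction claims into courses
#'
#' Consecutive fractions separated by at most `rt_course_merge_gap_days`
#' days form one course; the course start/end are the first/last fraction
#' and the fraction count is recorded.
#'
#' @param dates Date vector of fraction claims (one per fraction day).
#' @param config [window_config()].
#' @return tibble with `start`, `end`, `fraction_count`.
#' @export
build_rt_courses <- function(dates, config = window_config()) {
  if (length(dates) == 0) {
    return(tibble(start = as.Date(character(0)), end = as.Date(character(0)),
                  fraction_count = integer(0)))
  }
  dates <- sort(unique(dates))
  gap <- c(0L, days_between(dates[-length(dates)], dates[-1]))
  course <- cumsum(gap > config$rt_course_merge_gap_days)
  starts <- tapply(dates, course, min)
  ends <- tapply(dates, course, max)
  tibble(
    start = as.Date(as.vector(starts), origin = "1970-01-01"),
    end = as.Date(as.vector(ends), origin = "1970-01-01"),
    fraction_count = as.integer(tapply(dates, course, length))
  )
}

# Split one agent's administration dates into runs broken by >gap_days
# lapses; returns data.frame(agent, start, end) in date order.
agent_runs <- function(agent, dates, gap_days) {
  dates <- sort(unique(dates))
  gap <- c(0L, days_between(dates[-length(dates)], dates[-1]))
  run <- cumsum(gap > gap_days)
  data.frame(
    agent = agent,
    start = as.Date(as.vector(tapply(dates, run, min)), origin = "1970-01-01"),
    end = as.Date(as.vector(tapply(dates, run, max)), origin = "1970-01-01")
  )
}

#' Group drug administrations into systemic regimen blocks
#'
#' The first administration of the first agent anchors a regimen; any agent
#' whose own first administration (of its current run) falls within
#' `combo_window_days` of the anchor joins the component set. A block ends
#' at the last administration of any component before a more than
#' `gap_days` lapse; later administrations anchor new blocks.
#'
#' @param drugs tibble with `date` and `agent` for one patient.
#' @param config [window_config()].
#' @return tibble with `start`, `end` and a list-column `components`.
#' @export
build_systemic_regimens <- function(drugs, config = window_config()) {
  empty <- tibble(start = as.Date(character(0)), end = as.Date(character(0)),
                  components = list())
  if (nrow(drugs) == 0) return(empty)
  runs <- do.call(rbind, Map(agent_runs,
                             names(split(drugs$date, drugs$agent)),
                             split(drugs$date, drugs$agent),
                             MoreArgs = list(gap_days = config$gap_days)))
  runs <- runs[order(runs$start, runs$agent, method = "radix"), , drop = FALSE]
  assigned <- rep(FALSE, nrow(runs))
  blocks <- list()
  while (!all(assigned)) {
    anchor <- which(!assigned)[1]
    members <- which(!assigned &
                       days_between(runs$start[anchor], runs$start) >= 0 &
                       days_between(runs$start[anchor], runs$start) <= config$combo_window_days)
    assigned[members] <- TRUE
    blocks[[length(blocks) + 1]] <- list(
      start = runs$start[anchor],
      end = max(runs$end[members]),
      components = sort(unique(runs$agent[members]))
    )
  }
  tibble(
    start = as.Date(vapply(blocks, function(b) as.numeric(b$start), 0),
                    origin = "1970-01-01"),
    end = as.Date(vapply(blocks, function(b) as.numeric(b$end), 0),
                  origin = "1970-01-01"),
    components = lapply(blocks, `[[`, "components")
  )
}

#' Pair systemic blocks with radiotherapy courses as concurrent CRT
#'
#' A systemic block and a radiotherapy course are paired when their start
#' dates lie within `concurrent_window_days` of each other. Each block pairs
#' with at most one partner; when several qualify the nearest start wins,
#' ties going to the earlier block.
#'
#' @param blocks tibble of blocks with `modality`, `start` columns (as
#'   produced by [derive_timeline()] internals); rows of other modalities
#'   pass through.
#' @param config [window_config()].
#' @return `blocks` with an integer `pair` column (row index of the partner,
#'   `NA` if unpaired).
#' @export
pair_concurrent_crt <- function(blocks, config = window_config()) {
  blocks$pair <- rep(NA_integer_, nrow(blocks))
  sys_idx <- which(blocks$modality == "systemic")
  rt_idx <- which(blocks$modality == "radiotherapy")
  if (length(sys_idx) == 0 || length(rt_idx) == 0) return(blocks)
  cand <- expand.grid(s = sys_idx, r = rt_idx)
  cand$gap <- abs(days_between(blocks$start[cand$s], blocks$start[cand$r]))
  cand <- cand[cand$gap <= config$concurrent_window_days, , drop = FALSE]
  # nearest start first; ties resolved toward the earlier partner block
  cand <- cand[order(cand$gap,
                     pmin(as.numeric(blocks$start[cand$s]),
                          as.numeric(blocks$start[cand$r])),
                     cand$s, cand$r), , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    s <- cand$s[i]; r <- cand$r[i]
    if (is.na(blocks$pair[s]) && is.na(blocks$pair[r])) {
      blocks$pair[s] <- r
      blocks$pair[r] <- s
    }
  }
  blocks
}

# modality rank used for same-day ordering: surgery < systemic < radiotherapy
modality_rank <- function(modality) {
  match(modality, c("surgery", "systemic", "radiotherapy"))
}

#' Derive one patient's treatment timeline
#'
#' Runs the full sequencing algorithm for a single patient: block building,
#' CRT pairing, the 183-day treated rule, the 90-day LA-treatment window and
#' line-end detection.
#'
#' @param surgeries Date vector of resection procedure claims.
#' @param rt_fractions Date vector of radiotherapy fraction claims.
#' @param drugs tibble with `date`, `agent`.
#' @param index_date the patient's index date.
#' @param observation_end last date the patient is observed (enrollment end).
#' @param config [window_config()].
#' @param neck_dissections Date vector of neck dissection claims (used by the
#'   classifier's chemotherapy + neck dissection bucket).
#' @return an `hnc_timeline`: list with `blocks` (LA treatment), `after`
#'   (blocks beyond the 90-day window), `treated`, `first_treatment_date`,
#'   `line_end` (`ongoing`, `switched` or `discontinued`) and
#'   `line_end_date`.
#' @export
derive_timeline <- function(surgeries, rt_fractions, drugs, index_date,
                            observation_end, config = window_config(),
                            neck_dissections = as.Date(character(0))) {
  rt <- build_rt_courses(rt_fractions, config)
  sys <- build_systemic_regimens(drugs, config)
  n_srg <- length(surgeries)
  blocks <- tibble(
    modality = c(rep("surgery", n_srg),
                 rep("radiotherapy", nrow(rt)),
                 rep("systemic", nrow(sys))),
    start = c(as.Date(surgeries), rt$start, sys$start),
    end = c(as.Date(surgeries), rt$end, sys$end),
    components = c(rep(list("surgery"), n_srg),
                   rep(list("rt_course"), nrow(rt)),
                   sys$components),
    fraction_count = c(rep(NA_integer_, n_srg), rt$fraction_count,
                       rep(NA_integer_, nrow(sys)))
  )
  blocks <- blocks[order(blocks$start, modality_rank(blocks$modality),
                         method = "radix"), , drop = FALSE]
  blocks <- pair_concurrent_crt(blocks, config)

  timeline <- list(
    index_date = index_date,
    blocks = blocks[0, , drop = FALSE],
    after = blocks[0, , drop = FALSE],
    treated = FALSE,
    first_treatment_date = as.Date(NA),
    line_end = "ongoing",
    line_end_date = as.Date(NA),
    has_neck_dissection = length(neck_dissections) > 0
  )
  class(timeline) <- "hnc_timeline"
  if (nrow(blocks) == 0) {
    timeline$line_end <- "discontinued"
    timeline$line_end_date <- index_date
    return(timeline)
  }

  first_start <- blocks$start[1]
  timeline$first_treatment_date <- first_start
  timeline$treated <- days_between(index_date, first_start) >= 0 &&
    days_between(index_date, first_start) <= config$treated_window_days
  if (!timeline$treated) {
    timeline$after <- blocks
    return(timeline)
  }

  in_window <- days_between(first_start, blocks$start) <= config$modality_window_days
  # a concurrent partner of an in-window block is kept with it
  partnered <- !is.na(blocks$pair) & in_window[ifelse(is.na(blocks$pair), 1L, blocks$pair)]
  keep <- in_window | partnered
  la <- blocks[keep, , drop = FALSE]
  after <- blocks[!keep, , drop = FALSE]
  # re-map pair indices to row positions within the LA subset
  la$pair <- match(la$pair, which(keep))
  after$pair <- rep(NA_integer_, nrow(after))
  timeline$blocks <- la
  timeline$after <- after

  le <- detect_line_end(la, after, observation_end, config)
  timeline$line_end <- le$line_end
  timeline$line_end_date <- le$date
  timeline
}

#' Determine how the LA treatment line ended
#'
#' Applies the switch / discontinuation / add-on rules to the assembled LA
#' treatment: a monotherapy switch requires a different single agent starting
#' at least 8 days after the current start and within 60 days of the current
#' end; a combination switch removes one component and adds a new one within
#' 60 days, the new combination persisting at least 8 days; a lapse of more
#' than 60 treatment-free days with no qualifying successor is a
#' discontinuation; an agent joining while the current treatment continues
#' (add-on) neither ends nor advances the line.
#'
#' @param la_blocks LA-treatment blocks (tibble as in [derive_timeline()]).
#' @param later_blocks blocks beyond the 90-day window.
#' @param observation_end last observed date.
#' @param config [window_config()].
#' @return list with `line_end` and `date`.
#' @export
detect_line_end <- function(la_blocks, later_blocks, observation_end,
                            config = window_config()) {
  if (nrow(la_blocks) == 0) {
    return(list(line_end = "discontinued", date = as.Date(NA)))
  }
  cur_end <- max(la_blocks$end)
  # the reference block for agent-level switch rules is the last systemic
  # block of the LA treatment when one exists, else the last block overall
  sys_rows <- which(la_blocks$modality == "systemic")
  ref <- if (length(sys_rows) > 0) sys_rows[length(sys_rows)] else nrow(la_blocks)
  cur_start <- la_blocks$start[ref]
  cur_components <- la_blocks$components[[ref]]

  if (nrow(later_blocks) > 0) {
    for (i in order(later_blocks$start)) {
      succ_start <- later_blocks$start[i]
      succ_components <- later_blocks$components[[i]]
      gap_from_end <- days_between(cur_end, succ_start)
      if (gap_from_end > config$gap_days) break
      if (succ_start <= cur_end) next  # overlapping start: add-on, not a switch
      started_late_enough <- days_between(cur_start, succ_start) >= config$combo_window_days
      if (!started_late_enough) next
      if (length(cur_components) == 1 && length(succ_components) == 1 &&
          !identical(succ_components, cur_components)) {
        return(list(line_end = "switched", date = succ_start))
      }
      removed <- setdiff(cur_components, succ_components)
      added <- setdiff(succ_components, cur_components)
      persists <- days_between(succ_start, later_blocks$end[i]) >= config$combo_window_days
      if (length(removed) > 0 && length(added) > 0 && persists) {
        return(list(line_end = "switched", date = succ_start))
      }
    }
  }
  if (days_between(cur_end, observation_end) > config$gap_days) {
    return(list(line_end = "discontinued", date = cur_end))
  }
  list(line_end = "ongoing", date = as.Date(NA))
}

#' Derive treatment timelines for a cohort
#'
#' Splits the claims tables by patient and runs [derive_timeline()] for each
#' cohort member, returning one row per patient with the timeline as a
#' list-column plus convenience columns used by the classifier.
#'
#' @param claims an `hnc_claims` object.
#' @param cohort tibble with at least `patient_id` and `index_date`
#'   (typically the eligible rows of [select_cohort()] output).
#' @param config [window_config()].
#' @return tibble with `patient_id`, `index_date`, `treated`,
#'   `first_treatment_date`, `line_end` and list-column `timeline`.
#' @export
derive_timelines <- function(claims, cohort, config = window_config()) {
  stopifnot(inherits(claims, "hnc_claims"))
  ids <- cohort$patient_id
  obs_end <- claims$patients$enroll_end[match(ids, claims$patients$patient_id)]

  proc <- claims$procedures
  srg <- split(proc$date[proc$category == "surgery_resection"],
               proc$patient_id[proc$category == "surgery_resection"])
  nd <- split(proc$date[proc$category == "neck_dissection"],
              proc$patient_id[proc$category == "neck_dissection"])
  rt <- split(proc$date[proc$category == "radiotherapy_fraction"],
              proc$patient_id[proc$category == "radiotherapy_fraction"])
  # systemic therapy = antineoplastic administrations; all-cause prescription
  # rows (agent "other" without an antineoplastic L01 ATC code) are resource
  # events only and never enter episode derivation
  systemic <- claims$drugs$agent != "other" |
    (!is.na(claims$drugs$atc) & startsWith(claims$drugs$atc, "L01"))
  drug_claims <- claims$drugs[systemic, , drop = FALSE]
  drg <- split(drug_claims[c("date", "agent")], drug_claims$patient_id)

  empty_dates <- as.Date(character(0))
  empty_drugs <- tibble(date = empty_dates, agent = character(0))
  timelines <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    timelines[[k]] <- derive_timeline(
      surgeries = srg[[id]] %||% empty_dates,
      rt_fractions = rt[[id]] %||% empty_dates,
      drugs = drg[[id]] %||% empty_drugs,
      index_date = cohort$index_date[k],
      observation_end = obs_end[k],
      config = config,
      neck_dissections = nd[[id]] %||% empty_dates
    )
  }
  tibble(
    patient_id = ids,
    index_date = cohort$index_date,
    treated = map_lgl(timelines, "treated"),
    first_treatment_date = as.Date(map_dbl(timelines, function(t)
      as.numeric(t$first_treatment_date)), origin = "1970-01-01"),
    line_end = map_chr(timelines, "line_end"),
    timeline = timelines
  )
}
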
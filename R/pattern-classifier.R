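## Two-level treatment-pattern taxonomy.
##
## top level                     sub-sequences
## primary_resection             surgery_alone, surgery_then_crt,
##                               surgery_then_rt, chemo_then_surgery,
##                               other_resection
## definitive_nonsurgical        crt_alone, rt_alone, chemo_then_rt,
##                               rt_then_chemo
## chemo_neck_dissection         none
## not_treated                   none

pattern_tops <- c("primary_resection", "definitive_nonsurgical",
                  "chemo_neck_dissection", "not_treated")
pattern_subs <- c("surgery_alone", "surgery_then_crt", "surgery_then_rt",
                  "chemo_then_surgery", "other_resection", "crt_alone",
                  "rt_alone", "chemo_then_rt", "rt_then_chemo", "none")

sub_to_top <- c(
  surgery_alone = "primary_resection", surgery_then_crt = "primary_resection",
  surgery_then_rt = "primary_resection", chemo_then_surgery = "primary_resection",
  other_resection = "primary_resection", crt_alone = "definitive_nonsurgical",
  rt_alone = "definitive_nonsurgical", chemo_then_rt = "definitive_nonsurgical",
  rt_then_chemo = "definitive_nonsurgical"
)

# Collapse an LA-treatment block table into ordered sequence elements:
# one surgery element (multiple resections collapse), CRT units (paired
# systemic + radiotherapy, start = earlier of the two), remaining courses
# and regimens as their own elements.
sequence_elements <- function(blocks) {
  if (nrow(blocks) == 0) {
    return(tibble(kind = character(0), start = as.Date(character(0)),
                  components = list()))
  }
  used <- rep(FALSE, nrow(blocks))
  kinds <- character(0); starts <- as.Date(character(0)); comps <- list()
  push <- function(kind, start, components) {
    kinds <<- c(kinds, kind); starts <<- c(starts, start)
    comps[[length(comps) + 1]] <<- components
  }
  srg <- which(blocks$modality == "surgery")
  if (length(srg) > 0) {
    push("surgery", min(blocks$start[srg]), "surgery")
    used[srg] <- TRUE
  }
  for (i in which(!used)) {
    if (used[i]) next
    p <- blocks$pair[i]
    if (!is.na(p) && !used[p]) {
      push("crt", min(blocks$start[c(i, p)]),
           unique(unlist(blocks$components[c(i, p)])))
      used[c(i, p)] <- TRUE
    } else if (is.na(p)) {
      push(ifelse(blocks$modality[i] == "radiotherapy", "rt", "systemic"),
           blocks$start[i], blocks$components[[i]])
      used[i] <- TRUE
    }
  }
  ord <- order(starts, match(kinds, c("surgery", "crt", "systemic", "rt")),
               method = "radix")
  tibble(kind = kinds[ord], start = starts[ord], components = comps[ord])
}

#' Classify one timeline into the pattern taxonomy
#'
#' Maps an assembled treatment timeline to its `(top, sub)` pattern label:
#' untreated patients go to `not_treated`; timelines containing surgery go to
#' `primary_resection` with the sub-label read off the element order
#' (three-element or otherwise unmappable surgical sequences fall into
#' `other_resection`); surgery-free timelines go to `definitive_nonsurgical`
#' by the position of radiotherapy relative to non-concurrent systemic
#' therapy; systemic-only timelines with a neck dissection form the
#' chemotherapy + neck dissection bucket.
#'
#' @param timeline an `hnc_timeline` from [derive_timeline()].
#' @return list with `top`, `sub` and the element `sequence` string.
#' @export
classify_timeline <- function(timeline) {
  stopifnot(inherits(timeline, "hnc_timeline"))
  if (!timeline$treated) {
    return(list(top = "not_treated", sub = "none", sequence = ""))
  }
  el <- sequence_elements(timeline$blocks)
  # consecutive duplicates (e.g. two split radiotherapy courses) collapse
  keep <- c(TRUE, el$kind[-1] != el$kind[-nrow(el)])
  kinds <- el$kind[keep]
  seq_str <- paste(kinds, collapse = " -> ")

  if ("surgery" %in% kinds) {
    sub <- if (identical(kinds, "surgery")) "surgery_alone"
    else if (identical(kinds, c("surgery", "crt"))) "surgery_then_crt"
    else if (identical(kinds, c("surgery", "rt"))) "surgery_then_rt"
    else if (identical(kinds, c("systemic", "surgery"))) "chemo_then_surgery"
    else "other_resection"
    return(list(top = "primary_resection", sub = sub, sequence = seq_str))
  }
  if (all(kinds == "systemic")) {
    if (!timeline$has_neck_dissection) {
      warn(sprintf(
        "chemotherapy-only timeline without neck dissection (sequence: %s); such patients are normally excluded by the cohort cascade",
        seq_str))
    }
    return(list(top = "chemo_neck_dissection", sub = "none", sequence = seq_str))
  }
  first_rt_like <- which(kinds %in% c("rt", "crt"))[1]
  has_prior_systemic <- any(kinds[seq_len(first_rt_like - 1)] == "systemic")
  sub <- if (has_prior_systemic) {
    "chemo_then_rt"  # induction before (chemo)radiotherapy, concurrent or not
  } else if (kinds[first_rt_like] == "crt") {
    "crt_alone"
  } else if (any(kinds[-seq_len(first_rt_like)] %in% c("systemic", "crt"))) {
    "rt_then_chemo"
  } else {
    "rt_alone"
  }
  list(top = "definitive_nonsurgical", sub = sub, sequence = seq_str)
}

#' Classify all cohort timelines
#'
#' @param timelines output of [derive_timelines()].
#' @return tibble with `patient_id`, `top`, `sub`, `sequence`.
#' @export
classify_cohort <- function(timelines) {
  labels <- lapply(timelines$timeline, classify_timeline)
  tibble(
    patient_id = timelines$patient_id,
    top = factor(map_chr(labels, "top"), levels = pattern_tops),
    sub = factor(map_chr(labels, "sub"), levels = pattern_subs),
    sequence = map_chr(labels, "sequence")
  )
}

#' Tabulate treatment patterns by stratum
#'
#' Counts and one-decimal percentages of pattern labels, overall or
#' stratified by site, stage, age band or top-level (primary) treatment.
#' Within each stratum the percentages are of the stratum N; optionally the
#' not-treated group is excluded from the denominators, as done in the
#' site-within-stage presentation.
#'
#' @param labels output of [classify_cohort()].
#' @param cohort cohort records carrying the stratifier columns
#'   (`site`, `stage`, `age_band`).
#' @param by one of `"overall"`, `"site"`, `"stage"`, `"age"`,
#'   `"primary_treatment"`.
#' @param level `"top"` or `"sub"` — which taxonomy level to tabulate.
#' @param exclude_not_treated drop not-treated patients from the
#'   denominators.
#' @return a `hnc_pattern_table`: tibble with `stratum`, `label`, `n`,
#'   `pct`, `cell`.
#' @export
tabulate_patterns <- function(labels, cohort = NULL,
                              by = c("overall", "site", "stage", "age",
                                     "primary_treatment"),
                              level = c("top", "sub"),
                              exclude_not_treated = FALSE) {
  by <- match.arg(by)
  level <- match.arg(level)
  df <- labels
  if (by %in% c("site", "stage", "age")) {
    if (is.null(cohort)) abort("`cohort` is required for this stratifier")
    col <- switch(by, site = "site", stage = "stage", age = "age_band")
    df <- dplyr::left_join(df, cohort[c("patient_id", col)], by = "patient_id")
    df$stratum <- as.character(df[[col]])
  } else if (by == "primary_treatment") {
    df$stratum <- as.character(df$top)
  } else {
    df$stratum <- "overall"
  }
  if (exclude_not_treated) df <- df[df$top != "not_treated", , drop = FALSE]
  df$label <- as.character(df[[level]])
  lvls <- if (level == "top") pattern_tops else pattern_subs
  counts <- df |>
    dplyr::count(.data$stratum, label = factor(.data$label, levels = lvls),
                 .drop = FALSE) |>
    dplyr::mutate(label = as.character(.data$label))
  out <- report_counts(counts)
  structure(out, class = c("hnc_pattern_table", class(out)),
            by = by, level = level)
}

#' Regimen frequency distribution within a treatment context
#'
#' Tabulates canonical regimen names (component multiset rendered in the
#' conventional display order, e.g. `"fluorouracil + cisplatin +
#' docetaxel"`) among the patients whose derived pattern matches the
#' requested context: the systemic component of concurrent CRT
#' (`crt_backbone`), induction chemotherapy before surgery or before
#' radiotherapy, or the systemic component of adjuvant CRT after surgery
#' (`adjuvant_crt`).
#'
#' @param timelines output of [derive_timelines()].
#' @param labels output of [classify_cohort()].
#' @param context one of `"crt_backbone"`, `"induction_pre_surgery"`,
#'   `"induction_pre_rt"`, `"adjuvant_crt"`.
#' @return tibble with `regimen`, `n`, `pct`, `cell` over the context
#'   subgroup.
#' @export
regimen_distribution <- function(timelines, labels,
                                 context = c("crt_backbone",
                                             "induction_pre_surgery",
                                             "induction_pre_rt",
                                             "adjuvant_crt")) {
  context <- match.arg(context)
  target_sub <- switch(context,
    crt_backbone = "crt_alone",
    induction_pre_surgery = "chemo_then_surgery",
    induction_pre_rt = "chemo_then_rt",
    adjuvant_crt = "surgery_then_crt"
  )
  ids <- labels$patient_id[labels$sub == target_sub]
  rows <- timelines[timelines$patient_id %in% ids, , drop = FALSE]
  regimens <- map_chr(rows$timeline, function(t) {
    el <- sequence_elements(t$blocks)
    pick <- switch(context,
      crt_backbone = which(el$kind == "crt")[1],
      adjuvant_crt = which(el$kind == "crt")[1],
      induction_pre_surgery = which(el$kind == "systemic")[1],
      induction_pre_rt = which(el$kind %in% c("systemic", "crt"))[1]
    )
    if (is.na(pick)) return(NA_character_)
    comps <- setdiff(el$components[[pick]], "rt_course")
    regimen_name(comps)
  })
  regimens <- regimens[!is.na(regimens)]
  counts <- tibble(label = regimens) |>
    dplyr::count(.data$label, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$label) |>
    dplyr::rename(regimen = "label")
  counts$pct <- if (nrow(counts) > 0 && sum(counts$n) > 0) {
    round_half_up(100 * counts$n / sum(counts$n), 1)
  } else numeric(0)
  counts$cell <- if (nrow(counts) > 0) {
    format_count_pct(counts$n, sum(counts$n))
  } else character(0)
  counts
}
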
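# Independent brute-force scanner for the sequencing rules, used to
# cross-check the episode engine. Everything here works on integer day
# numbers with explicit loops over days and event pairs; no code is shared
# with the package implementation.

# split one agent's administration days into runs by scanning day by day
oracle_agent_runs <- function(days, gap_days) {
  days <- sort(unique(as.integer(days)))
  runs <- list()
  run_start <- days[1]
  prev <- days[1]
  for (d in days[-1]) {
    if (d - prev > gap_days) {
      runs[[length(runs) + 1]] <- c(run_start, prev)
      run_start <- d
    }
    prev <- d
  }
  runs[[length(runs) + 1]] <- c(run_start, prev)
  runs
}

# radiotherapy courses by the same scan
oracle_rt_courses <- function(days, merge_gap) {
  if (length(days) == 0) return(list())
  runs <- oracle_agent_runs(days, merge_gap)
  days <- sort(unique(as.integer(days)))
  lapply(runs, function(r) {
    list(start = r[1], end = r[2], n = sum(days >= r[1] & days <= r[2]))
  })
}

# systemic blocks: exhaustively anchor the earliest unassigned run and test
# every other run against the combination window
oracle_systemic_blocks <- function(drugs_days, combo_window, gap_days) {
  # drugs_days: data.frame(day, agent)
  if (nrow(drugs_days) == 0) return(list())
  runs <- data.frame(agent = character(0), start = integer(0), end = integer(0))
  for (ag in sort(unique(drugs_days$agent))) {
    for (r in oracle_agent_runs(drugs_days$day[drugs_days$agent == ag], gap_days)) {
      runs <- rbind(runs, data.frame(agent = ag, start = r[1], end = r[2]))
    }
  }
  blocks <- list()
  repeat {
    if (nrow(runs) == 0) break
    anchor <- min(runs$start)
    # ties on the anchor date: all runs starting that day share the block
    member <- rep(FALSE, nrow(runs))
    for (i in seq_len(nrow(runs))) {
      if (runs$start[i] - anchor >= 0 && runs$start[i] - anchor <= combo_window) {
        member[i] <- TRUE
      }
    }
    blocks[[length(blocks) + 1]] <- list(
      start = anchor, end = max(runs$end[member]),
      components = sort(unique(runs$agent[member]))
    )
    runs <- runs[!member, , drop = FALSE]
  }
  blocks
}

# CRT pairing: repeatedly scan every (systemic, radiotherapy) pair for the
# closest qualifying starts, ties resolved toward the earlier block
oracle_crt_pairs <- function(sys_starts, rt_starts, concurrent_window) {
  used_s <- rep(FALSE, length(sys_starts))
  used_r <- rep(FALSE, length(rt_starts))
  pairs <- list()
  repeat {
    best <- NULL
    for (i in seq_along(sys_starts)) {
      for (j in seq_along(rt_starts)) {
        if (used_s[i] || used_r[j]) next
        gap <- abs(sys_starts[i] - rt_starts[j])
        if (gap > concurrent_window) next
        key <- c(gap, min(sys_starts[i], rt_starts[j]), sys_starts[i], rt_starts[j])
        if (is.null(best) || isTRUE(vector_less(key, best$key))) {
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    if (is.null(best)) break
    used_s[best$i] <- TRUE
    used_r[best$j] <- TRUE
    pairs[[length(pairs) + 1]] <- c(sys = sys_starts[best$i], rt = rt_starts[best$j])
  }
  pairs
}

vector_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

# full oracle derivation for one patient given day offsets from index
oracle_timeline <- function(surgery_days, rt_days, drugs_days, obs_end_day,
                            cfg = window_config()) {
  blocks <- list()
  for (d in sort(as.integer(surgery_days))) {
    blocks[[length(blocks) + 1]] <- list(modality = "surgery", start = d,
                                         end = d, components = "surgery")
  }
  for (b in oracle_rt_courses(rt_days, cfg$rt_course_merge_gap_days)) {
    blocks[[length(blocks) + 1]] <- list(modality = "radiotherapy",
                                         start = b$start, end = b$end,
                                         components = "rt_course")
  }
  for (b in oracle_systemic_blocks(drugs_days, cfg$combo_window_days,
                                   cfg$gap_days)) {
    blocks[[length(blocks) + 1]] <- list(modality = "systemic", start = b$start,
                                         end = b$end,
                                         components = b$components)
  }
  if (length(blocks) == 0) {
    return(list(treated = FALSE, la = list(), after = list(), pairs = list(),
                line_end = "discontinued"))
  }
  starts <- sapply(blocks, `[[`, "start")
  rank <- match(sapply(blocks, `[[`, "modality"),
                c("surgery", "systemic", "radiotherapy"))
  blocks <- blocks[order(starts, rank)]
  starts <- sapply(blocks, `[[`, "start")

  first <- starts[1]
  treated <- first >= 0 && first <= cfg$treated_window_days
  if (!treated) {
    return(list(treated = FALSE, la = list(), after = blocks, pairs = list(),
                line_end = "ongoing"))
  }
  sys_starts <- starts[sapply(blocks, `[[`, "modality") == "systemic"]
  rt_starts <- starts[sapply(blocks, `[[`, "modality") == "radiotherapy"]
  pairs <- oracle_crt_pairs(sys_starts, rt_starts, cfg$concurrent_window_days)

  paired_partner_in <- function(b) {
    for (p in pairs) {
      partner <- if (b$modality == "systemic" && b$start == p[["sys"]]) p[["rt"]]
      else if (b$modality == "radiotherapy" && b$start == p[["rt"]]) p[["sys"]]
      else next
      if (partner - first <= cfg$modality_window_days) return(TRUE)
    }
    FALSE
  }
  la <- list(); after <- list()
  for (b in blocks) {
    if (b$start - first <= cfg$modality_window_days || paired_partner_in(b)) {
      la[[length(la) + 1]] <- b
    } else {
      after[[length(after) + 1]] <- b
    }
  }

  # line end: test every later block against the switch definitions
  cur_end <- max(sapply(la, `[[`, "end"))
  sys_la <- Filter(function(b) b$modality == "systemic", la)
  ref <- if (length(sys_la) > 0) sys_la[[length(sys_la)]] else la[[length(la)]]
  line_end <- NULL
  for (b in after[order(sapply(after, `[[`, "start"))]) {
    gap <- b$start - cur_end
    if (gap > cfg$gap_days) break
    if (b$start <= cur_end) next
    if (b$start - ref$start < cfg$combo_window_days) next
    mono_switch <- length(ref$components) == 1 && length(b$components) == 1 &&
      !identical(b$components, ref$components)
    combo_switch <- length(setdiff(ref$components, b$components)) > 0 &&
      length(setdiff(b$components, ref$components)) > 0 &&
      (b$end - b$start) >= cfg$combo_window_days
    if (mono_switch || combo_switch) {
      line_end <- "switched"
      break
    }
  }
  if (is.null(line_end)) {
    line_end <- if (obs_end_day - cur_end > cfg$gap_days) "discontinued"
    else "ongoing"
  }
  list(treated = TRUE, la = la, after = after, pairs = pairs,
       line_end = line_end)
}

# canonical comparable forms ------------------------------------------------

block_signature <- function(modality, start, end, components) {
  paste(modality, start, end, paste(sort(components), collapse = "+"),
        sep = "|")
}

oracle_signatures <- function(blocks) {
  sort(vapply(blocks, function(b) {
    block_signature(b$modality, b$start, b$end, b$components)
  }, ""))
}

engine_signatures <- function(blocks_tbl, index_day0) {
  if (nrow(blocks_tbl) == 0) return(character(0))
  sort(vapply(seq_len(nrow(blocks_tbl)), function(i) {
    block_signature(blocks_tbl$modality[i],
                    as.integer(blocks_tbl$start[i]) - index_day0,
                    as.integer(blocks_tbl$end[i]) - index_day0,
                    blocks_tbl$components[[i]])
  }, ""))
}

engine_pair_signatures <- function(blocks_tbl, index_day0) {
  if (nrow(blocks_tbl) == 0) return(character(0))
  out <- character(0)
  for (i in seq_len(nrow(blocks_tbl))) {
    p <- blocks_tbl$pair[i]
    if (!is.na(p) && blocks_tbl$modality[i] == "systemic") {
      out <- c(out, paste(as.integer(blocks_tbl$start[i]) - index_day0,
                          as.integer(blocks_tbl$start[p]) - index_day0,
                          sep = "~"))
    }
  }
  sort(out)
}

oracle_pair_signatures <- function(pairs) {
  sort(vapply(pairs, function(p) paste(p[["sys"]], p[["rt"]], sep = "~"), ""))
}

# random small event set (day offsets from index) for property tests
random_event_set <- function(max_events = 12) {
  n_srg <- sample(0:2, 1)
  n_rt_clusters <- sample(0:2, 1)
  n_drug <- sample(0:(max_events - n_srg - n_rt_clusters), 1)
  surgery <- sample(0:180, n_srg, replace = TRUE)
  rt <- integer(0)
  for (k in seq_len(n_rt_clusters)) {
    s <- sample(0:170, 1)
    rt <- c(rt, s + cumsum(c(0, sample(1:20, sample(1:4, 1), replace = TRUE))))
  }
  drugs <- if (n_drug > 0) {
    data.frame(day = sample(0:220, n_drug, replace = TRUE),
               agent = sample(c("cisplatin", "cetuximab", "fluorouracil"),
                              n_drug, replace = TRUE))
  } else {
    data.frame(day = integer(0), agent = character(0))
  }
  list(surgery = surgery, rt = rt, drugs = drugs,
       obs_end = sample(250:500, 1))
}

# run the engine on a day-offset event set (anchored at an arbitrary date)
engine_timeline_from_days <- function(ev, cfg = window_config()) {
  origin <- as.Date("2018-01-01")
  derive_timeline(
    surgeries = origin + ev$surgery,
    rt_fractions = origin + ev$rt,
    drugs = tibble::tibble(date = origin + ev$drugs$day,
                           agent = ev$drugs$agent),
    index_date = origin,
    observation_end = origin + ev$obs_end,
    config = cfg
  )
}
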
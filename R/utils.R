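## Controlled vocabularies shared across the pipeline ------------------------

# Tumour sites covered by the analysis (ICD-10 C01-C14 oral cavity/pharynx,
# C32 larynx), stage labels, and the systemic-agent vocabulary.
hnc_sites <- c("oral_cavity", "oropharynx", "hypopharynx", "larynx")
stage_levels <- c("I", "II", "III", "IVA", "IVB", "IVC")
la_stages <- c("III", "IVA", "IVB")

# Canonical agent display order: combination names are printed with agents in
# this precedence (so {cisplatin, docetaxel, fluorouracil} renders as
# "fluorouracil + cisplatin + docetaxel", the conventional TPF spelling).
agent_vocabulary <- c(
  "fluorouracil", "cetuximab", "cisplatin", "paclitaxel", "nedaplatin",
  "carboplatin", "docetaxel", "tegafur_gimeracil_oteracil", "other"
)

procedure_categories <- c(
  "surgery_resection", "neck_dissection", "radiotherapy_fraction",
  "physician_visit", "lab_test", "imaging", "rehab_homecare"
)

# ICD-10 prefixes defining each head-and-neck site. Oral cavity C00-C06,
# oropharynx C01/C09/C10 overlap is resolved by the site assignment used at
# generation time; for cohort selection only membership in the union matters.
hnc_code_prefixes <- list(
  oral_cavity = c("C02", "C03", "C04", "C05", "C06"),
  oropharynx  = c("C01", "C09", "C10"),
  hypopharynx = c("C12", "C13"),
  larynx      = c("C32")
)

metastasis_prefixes <- c("C78", "C79")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Fixed-point rounding used for all printed percentages, so that e.g.
#' 32.35 renders as 32.4 (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a count with its percentage
#'
#' Renders report cells in the `"n (p)"` style used throughout the output
#' tables, with the percentage at one decimal (half-up).
#'
#' @param n integer count(s).
#' @param total denominator (scalar or vector recycled against `n`).
#' @return character vector like `"3461 (51.3)"`.
#' @export
format_count_pct <- function(n, total) {
  total <- rep_len(total, length(n))
  pct <- ifelse(total > 0, round_half_up(100 * n / total, 1), 0)
  sprintf("%d (%.1f)", as.integer(n), pct)
}

#' Canonical regimen name from a set of agents
#'
#' Orders the component agents by the conventional display precedence and
#' joins them with `" + "`; duplicates are dropped. `character(0)` gives
#' `NA`.
#'
#' @param agents character vector of agent names.
#' @return a single canonical regimen string.
#' @export
regimen_name <- function(agents) {
  agents <- unique(agents)
  if (length(agents) == 0) return(NA_character_)
  known <- intersect(agent_vocabulary, agents)
  extra <- sort(setdiff(agents, agent_vocabulary))
  paste(c(known, extra), collapse = " + ")
}

# Whole-day difference between two Date vectors.
days_between <- function(from, to) as.integer(as.numeric(to) - as.numeric(from))

# Strip dots from ICD-10 codes so prefix matching is layout-independent.
icd_normalize <- function(code) gsub(".", "", toupper(code), fixed = TRUE)

# TRUE where `code` starts with any of `prefixes` (both dot-stripped).
icd_matches <- function(code, prefixes) {
  code <- icd_normalize(code)
  pre <- icd_normalize(prefixes)
  out <- rep(FALSE, length(code))
  for (p in pre) out <- out | startsWith(code, p)
  out
}

is_hnc_code <- function(code) icd_matches(code, unlist(hnc_code_prefixes))

assert_prob_vector <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("`%s` must be a non-negative vector summing to 1", what),
         call. = FALSE)
  }
  invisible(p)
}
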
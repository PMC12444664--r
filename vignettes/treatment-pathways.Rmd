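---
title: "Deriving treatment pathways from oncology claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving treatment pathways from oncology claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hncpatterns)
```

## The problem

Administrative claims encode care as dated billing events. For locally
advanced squamous cell carcinoma of the head and neck (LA SCCHN), the
clinically meaningful object — *the treatment strategy* (primary resection
with or without adjuvant therapy, definitive chemoradiotherapy, induction
chemotherapy followed by local therapy, or no treatment) — must be
reconstructed from those events by explicit temporal rules. This vignette
documents the rules as implemented, the conventions that pin down every
boundary case, the synthetic data the package tests itself against, and the
limits of what those tests demonstrate.

## Cohort selection

A patient enters the cohort at the **index date**: the earliest
head-and-neck cancer diagnosis date inside the diagnosis window
(2016-01-01 to 2021-06-30 by default) that is *confirmed* — at least one
inpatient claim, or at least two outpatient claims carrying a primary
diagnosis code — and *staged*, i.e. accompanied by a TNM stage III/IVA/IVB
claim within 60 days. Two readings were genuinely open:

* whether the stage claim may precede the diagnosis: the 60-day window is
  applied **unsigned** (±60 days), since staging workups commonly straddle
  the formal diagnosis date;
* whether both confirming outpatient claims must fall inside the diagnosis
  window: only the index claim must; the second claim may fall outside,
  because confirmation is evidence about the diagnosis, not about timing.

Exclusions are evaluated in a fixed cascade and only the **first** failing
criterion is recorded, so attrition counts are well defined: age < 18 at
index; any metastatic-disease code (C78.x/C79.x) before index; any stage
I/II/IVC claim before index; any other primary cancer during the pre-index
year; under 12 months of pre-index enrollment; chemotherapy as the only
treatment (unless a neck dissection was also performed); clinical-trial
participation. "Other primary cancer" is read narrowly: a C-code outside
the head-and-neck set and outside C78/C79, strictly before index and within
the look-back year. Trial participation is a boolean flag on the patient
record, since claims databases typically mark it out of band.

Lymph-node involvement is carried as a baseline column but reported as
`"unknown"`: the staging claims in this data model carry the stage group
only, and inventing an N-stage encoding would suggest information the data
do not contain.

## Comorbidity scoring

The Elixhauser Comorbidity Index is computed over 30 categories flagged by
ICD-10 prefix match (the standard ICD-10 coding of the Elixhauser measures,
with the two hypertension strata combined) and scored with van Walraven's
weights. The table ships as `inst/extdata/eci_weights.csv` — category,
weight, semicolon-separated prefixes — so it is inspectable and editable.
The positive weights sum to +89 and the negative weights to −19, which are
therefore the attainable score bounds; the test suite asserts both, and
scores a synthetic patient carrying one code from every category (score
+70 = 89 − 19). Only claims **strictly before** the index date and within
the 365-day look-back count; duplicate codes within a category count once.

## The sequencing engine

All window arithmetic is whole-day differences on calendar dates, with
"within *k* days" always inclusive (|Δ| ≤ *k*); months are fixed at
183 days (6 months) and 365 days (12 months) because claims carry day
resolution and month arithmetic is not reproducible. The constants, all
overridable via `window_config()`:

| constant | days | role |
|---|---|---|
| `combo_window_days` | 8 | agents joining a combination |
| `concurrent_window_days` | 14 | systemic/radiotherapy concurrency (CRT) |
| `gap_days` | 60 | block-ending lapse; switch window |
| `modality_window_days` | 90 | extent of the LA treatment |
| `treated_window_days` | 183 | treated vs not treated |
| `rt_course_merge_gap_days` | 14 | radiotherapy fraction merging |

Blocks are built per modality: radiotherapy fractions merge into courses
while inter-fraction gaps stay within 14 days; each systemic agent's
administrations split into runs at > 60-day lapses, the earliest unassigned
run anchors a regimen, and runs starting within 8 days of the anchor join
it. A systemic block and a radiotherapy course pair as concurrent CRT when
their **start dates** lie within 14 days; each block pairs at most once,
nearest start first, ties to the earlier block. Start dates — not overlap —
decide concurrency because that is how the rule is phrased clinically
(therapies *initiated* together), and it makes the rule monotone: widening
the window can only create pairs, never destroy them (a property test).

The LA treatment comprises all blocks starting within 90 days of the first
treatment, provided that first treatment began within 183 days of index.
Two deliberate conventions: a CRT partner of an in-window block is kept
even if its own start falls outside the 90 days, and a block that starts
inside the window runs to its own end rather than being truncated. Same-day
starts order surgery < systemic < radiotherapy — a tie-break that the
concurrency rules make almost irrelevant, but which must be pinned for
deterministic output. Multiple resections inside the window collapse into
one surgery element for labeling, since the taxonomy has no repeat-surgery
label.

Line end: a monotherapy switch requires a different single agent starting
≥ 8 days after the current start and ≤ 60 days after the current end; a
combination switch removes one component and adds another within 60 days
with the new combination persisting ≥ 8 days; a > 60-day treatment-free
lapse with no qualifying successor is a discontinuation; an agent joining
while the current treatment continues is an add-on and neither ends nor
advances the line. The switch rules compare the current block's **end** to
the successor's **start** (the lapse reading), while all other windows
compare starts. Because blocks starting within 90 days of the first belong
to the LA treatment itself, switch detection operates on blocks beyond that
window. The rules are applied uniformly to all modalities; how radiotherapy
"prescription gaps" should interact with the 60-day rule is not specified
anywhere, and uniformity is the only defensible default.

The engine's correctness case is not the unit examples but an
**independent brute-force oracle**: a day-by-day scanner in the test
helpers, sharing no code with the implementation, that exhaustively tests
every event pair against every rule. Engine and oracle agree on 1,000
random small event histories (≤ 12 events) in the acceptance suite — blocks,
CRT pairings and line end — and boundary fixtures place gaps of 8/9, 14/15,
60/61, 90/91 and 183/184 days on opposite sides of each rule.

## Classification

Untreated patients label `not_treated`. Otherwise the LA blocks collapse to
ordered sequence elements (surgery, CRT unit, radiotherapy course, systemic
block) and map to the two-level taxonomy. Conventions worth recording:

* *CRT alone* requires the paired unit with no preceding non-concurrent
  systemic block; induction followed by concurrent CRT classifies as
  *chemo → RT*, keeping "what came first" the discriminating feature.
* Surgical sequences that match no named pattern (three-modality sequences,
  surgery followed by chemotherapy alone) fall into `other_resection` — the
  "Other" row of the reported tables — with the element sequence retained
  for inspection.
* Systemic-only timelines reach the classifier only via the
  neck-dissection exception (chemotherapy-only patients are excluded by the
  cascade); they form the small chemotherapy + neck dissection bucket,
  which stays a separate top-level class because folding it into resection
  would corrupt both percentages.
* Regimen names render components in the conventional clinical order
  (`fluorouracil + cisplatin + docetaxel`, `cetuximab + paclitaxel +
  carboplatin`), not alphabetically.
* Percentages print at one decimal, rounded half away from zero, matching
  how published tables round; `report_counts()` asserts |cell − 100·n/N| ≤
  0.05 by construction.

## The synthetic generator

`generate_cohort()` emits claims with the statistical structure the
analysis assumes. Defaults are the study conditions: the 2015–2022 claims
calendar, the four-site and three-stage mixes, the published
treatment-pathway proportions (a definitive-nonsurgical share of 51.3%
across its four sub-sequences, resection 32.4%, untreated 16.1%), regimen
menus per context (cisplatin-dominant CRT backbones; induction menus in
which TPF carries 55.6% before radiotherapy and 28.6% before surgery), and
utilization/cost processes of the reported magnitudes (median 15 physician
visits, ~99.8% of patients admitted, admission-dominated expenditure).

Pathways are realized **constructively**: every gap is drawn inside the
legal range the label implies (induction-to-radiotherapy gaps from 15–80
days so they are sequential; CRT systemic anchors within 0–10 days of the
course start; successors of the not-treated label only after day 183).
There is no rejection sampling, so label closure is guaranteed by
construction and checked exhaustively: classification recovers the intended
label for 500 randomized realizations of every supported sub-sequence, and
eligibility verdicts match the truth table for 100% of patients on
contaminated cohorts.

Distribution families are a generator choice, documented here: counts are
negative binomial among users (dispersion chosen to match the reported
standard deviations), clipped to the reported min/max; costs are log-normal
(σ = 0.8 on the log scale) around per-event means derived from the
reported per-user means; comorbidity categories are independent Bernoulli
draws with probabilities chosen to give a mean index near the reported 2.25.
Ages are normal (67.7, 11.8) clipped to 20–99; follow-up is log-normal with
median ≈ 650 days, truncated at the calendar end. A root seed drives
per-patient child seeds, so cohorts are byte-identical under the same
configuration and prefix-stable when only `n_patients` changes.
Contaminants default to 20% of patients, spread across all seven exclusion
branches so the attrition cascade is fully exercised.

What the generator does **not** emulate — and what passing tests therefore
do not show: real comorbidity co-occurrence structure (categories are
independent), dose and cycle-length variation, hospital-level linkage
artifacts, mid-course regimen modifications beyond the realized labels,
per-fraction billing idiosyncrasies (one claim per fraction day is
assumed), fee-schedule unit prices, and any mortality process (death dates
are carried in the schema but not simulated). Recovery of configured
proportions on synthetic data validates the *algebra* of the pipeline, not
the clinical fidelity of any particular claims source.

## Resource use and costs

The eight categories count events in `[index, index + 365)` for patients
observed the full year (the boundary is sharp: 364 days of follow-up
excludes, 365 includes). Summaries are among users only. An admission
counts — with its full cost — when its admit date is inside the window,
because admissions are billed as single claims. All-cause prescriptions
include antineoplastic administrations; episode derivation, conversely,
uses only antineoplastic claims (named agents, or ATC L01), so attaching a
resource stream never changes classification — an invariant in the test
suite.

Cost per patient-year divides a stratum's total expenditure by its summed
follow-up **years**. The default denominator is the full (uncapped)
follow-up of the stratum's patients: published totals and per-patient-year
figures for this analysis are mutually consistent only under multi-year
denominators (total ÷ rate gives far more patient-years than patients).
`hcru_config(cost_py_denominator = "capped_1y")` selects the capped
alternative. Whether patients dying in hospital before 12 months belong in
the resource cohort is unstated in the source analysis; the default
requires the full window, and `require_full_window = FALSE` relaxes it.

## Problem sizes and numerical conventions

The test suite exercises the pipeline at 6,741 synthetic patients (the
published cohort size) for proportion recovery, 500 realizations per
pathway label for closure, 1,000 random histories for oracle equivalence,
and cohorts of 150–2,000 for module-level properties — sizes chosen so the
binomial tolerances (3 standard errors) are meaningful. Costs are integer
JPY end to end, summed in double precision; probability vectors must sum to
1 within 1e−9; all randomness flows from explicit integer seeds.

## Known limitations

* The claims schema is an idealization: real claims-extract layouts differ
  and must be mapped to the six documented tables first.
* Only the first treatment line is characterized; `detect_line_end`
  reports how the line ended but later lines are not assembled.
* The stage nearest the index date is taken as *the* stage; restaging
  during follow-up is ignored.
* BMI, histology and HPV status are not modeled; N-stage is reported as
  unknown (see above).
* The chemotherapy-only exclusion, faithfully implemented, removes
  genuinely squamous patients whose induction chemotherapy was never
  followed by documented local therapy — an acknowledged ambiguity of the
  rule itself.
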
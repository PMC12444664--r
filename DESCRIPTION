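Package: hncpatterns
Title: Treatment Patterns, Comorbidity and Resource Use from Oncology Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A claims-based analysis pipeline for locally advanced squamous
    cell carcinoma of the head and neck (LA SCCHN). Builds incident cohorts
    from longitudinal administrative claims tables (ICD-10 diagnoses, TNM
    staging, drug administrations, procedures, admissions), derives
    modality-level treatment episodes with rule-based temporal sequencing
    (concurrency, combination, switch, add-on and discontinuation windows),
    classifies patients into a two-level treatment-pattern taxonomy, scores
    baseline comorbidity with the Elixhauser index (van Walraven weights),
    and aggregates 12-month healthcare resource utilization and costs.
    Includes a seeded synthetic claims generator so the whole pipeline is
    testable without access to proprietary hospital claims databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
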
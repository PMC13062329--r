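Package: neurovigil
Title: Disproportionality Signal Detection for Immune Checkpoint
    Inhibitor Neurotoxicity in Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for pharmacovigilance analysis of
    neurological immune-related adverse events (n-irAEs) reported for
    immune checkpoint inhibitors (ICIs) in spontaneous-report databases
    distributed in the FAERS ASCII dialect. Reads quarterly
    dollar-delimited report packages, applies the FDA-recommended
    case-version deduplication and deletion-list rules, normalizes
    verbatim drug names through a synonym dictionary, maps reaction
    preferred terms through a MedDRA-style PT/HLGT/SOC hierarchy slice,
    produces cohort descriptive summaries, and detects disproportionality
    signals with the reporting odds ratio (ROR) and its 95 percent
    confidence interval, including stratified, monotherapy-sensitivity
    and combination-therapy analyses. A synthetic-data generator with
    planted signals and known ground truth makes every stage testable
    without access to the real database.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
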
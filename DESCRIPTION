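Package: slrepurpose
Title: Synthetic-Lethality Knowledge Graphs for Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an in-memory knowledge graph linking genes, drugs and
    cancer types through synthetic-lethality (SL) and synthetic-dosage-
    lethality (SDL) gene pairs, drug-target links, gene-disease scores and
    known indications. Prioritizes repurposable drug candidates with a
    three-part scoring schema (noisy-OR evidence aggregation, a drug
    development-status score and a gene-disease association score),
    normalizes and thresholds the scores, orders candidates by robust rank
    aggregation, validates them against cell-line drug-sensitivity data
    with one-sided Wilcoxon rank-sum tests, and mines two-drug combinations
    covering SL pairs of a shared mutant gene by exact optimization over a
    weighted bipartite graph. Includes a deterministic synthetic-data
    generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
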
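Package: phenoclaims
Title: Claims-Based Phenotyping of Pediatric Genetic-Disease Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies pediatric and critically-ill-newborn patients with
    clinical indicators of genetic disease from administrative healthcare
    claims. Provides a curated code-catalog layer (tiered ICD-9/10 diagnosis
    codes, CPT/HCPCS genetic-test and workup categories, NICU/PICU revenue
    codes), index-date and continuous-enrollment cohort algorithms for Broad,
    MCA/ID/DD/E and Conservative cohort definitions, coarsened exact matching
    with k-to-k pruning and the L1 multivariate imbalance measure, and outcome
    computation: genetic-test utilization, intensive-care utilization and
    length of stay, diagnostic-category transitions, and 30-day cost accrual
    from the index date. A synthetic claims generator with planted ground
    truth makes the whole pipeline testable without access to proprietary
    claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
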
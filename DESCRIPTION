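Package: doacaudit
Title: Audit of Direct-Acting Oral Anticoagulant Dosing Against Renal Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds monthly cohorts of adults prescribed a direct-acting oral
    anticoagulant (DOAC) from event-level primary-care records, extracts
    renal-function and weight parameters within a 12-month lookback, classifies
    each prescribed regimen against the creatinine-clearance-banded recommended
    dose table for atrial fibrillation, and reports monthly proportion measures
    and change summaries. Includes a Cockcroft-Gault creatinine-clearance
    calculator with configurable weight policy and a seeded synthetic
    electronic-health-record generator so the whole pipeline is testable
    without access to real records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    purrr,
    rlang,
    stats,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
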
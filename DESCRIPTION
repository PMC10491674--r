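Package: toxconcord
Title: Concordance of Short-Term and Long-Term Repeat-Dose Toxicity Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes in-vivo repeat-dose toxicity study findings into
    high-level categories using controlled terminology, summarizes overall
    adversity per molecule, classifies NOAEL (no observed adverse effect
    level) progression from short/mid-term to long-term studies, and
    quantifies short-to-long concordance of findings with 2x2 contingency
    tables, positive and inverse negative likelihood ratios, Fisher's exact
    tests and false-positive/false-negative frequencies. Includes a seeded
    synthetic-cohort generator with the same schema so the full workflow is
    testable without proprietary study data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
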
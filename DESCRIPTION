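Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event
    Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for pharmacovigilance signal screening on
    FAERS-style spontaneous adverse event report databases: quarterly
    ASCII table ingestion, case assembly, deduplication and cleaning,
    drug/indication cohort selection with MedDRA-style preferred-term to
    system-organ-class coding, descriptive comparison of report cohorts,
    and four disproportionality estimators (reporting odds ratio,
    proportional reporting ratio, the BCPNN information component, and
    the gamma-Poisson shrinker EBGM) with conventional signal thresholds,
    subgroup screens and heatmap matrices.  Includes a seeded synthetic
    report generator with implanted signals so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tools,
    utils,
    vctrs,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
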
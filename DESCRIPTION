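Package: raremetrics
Title: Cumulative Point Prevalence of Rare Diseases from Epidemiology
    Knowledge Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the cumulative point prevalence of rare diseases
    from an Orphanet-style epidemiology knowledge file. Implements entity
    deduplication across classification levels, indicator-based exclusion,
    geographic preference selection (worldwide, then Europe, then USA under
    the European rarity threshold), three-way treatment of prevalence
    evidence (numeric values, predefined prevalence classes, and case or
    family reports via an indirect estimate), minimum/maximum boundary
    aggregation, stratification by prevalence class, national
    rare-disease-definition coverage, and population extrapolation. Ships a
    seeded synthetic-data generator that emulates the statistical structure
    of the knowledge file together with a ground-truth manifest for
    parameter-recovery testing.
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
    stringr,
    tibble,
    tidyr,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
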
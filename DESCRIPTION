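Package: n2kgap
Title: Representation and Gap Analysis of Freshwater Habitats in the
    Natura 2000 Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Curates tabular exports of the Natura 2000 database (sites,
    Annex I habitat entries, biogeographic region percentages), applies an
    auditable sequence of exclusion rules, classifies Annex I habitats into
    freshwater, marine and coastal, and terrestrial classes (with freshwater
    groups and nutrient levels), assigns each site a terrestrial
    biogeographic region, infers each freshwater habitat's natural range
    from a European Red List of Habitats crosswalk, and computes coverage,
    size-distribution, nutrient and biogeographic representation-gap
    summaries. Includes a synthetic-data generator with planted anomalies
    and known ground truth so the whole pipeline is testable without any
    database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
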
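Package: ecotoxcurate
Title: Curation of Aquatic Effect Concentrations and Mode-of-Action Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to harvest, filter, and harmonize acute effect
    concentrations from ECOTOX-style knowledgebase releases for the three
    aquatic biological quality elements (algae, crustaceans, fish), to
    aggregate them into one robust value per chemical and species group,
    to classify results against predicted water solubility, and to
    post-process QSAR effect-concentration predictions. Also provides a
    data model, validation, and summary statistics for curated use-group
    and mode-of-action annotation catalogs, plus a seeded
    synthetic-fixture generator for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    zip
Config/testthat/edition: 3
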
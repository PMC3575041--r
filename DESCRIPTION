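Package: clingenmap
Title: Clinic-Genomic Relation Mining over UMLS-Style Terminology Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines candidate relations between clinical concepts (SNOMED
    CT-coded items) and genomic concepts (genes) through UMLS Rich Release
    Format terminology files. Implements direct information mapping (one-step
    relation and co-occurrence traversal filtered by semantic type) and
    indirect information mapping via shared disease concepts, validates
    candidate relations by MeSH-indexed literature co-occurrence, extracts
    disease gene, protein and article sets from OMIM-style snapshots by
    field-restricted boolean keyword search, and composes or parses SNOMED CT
    postcoordinated expressions. Ships a seeded synthetic-fixture generator
    with known ground truth so the whole pipeline is testable offline, and a
    command-line interface over the same functions.
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
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
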
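Package: mclabel
Title: Medical Condition Mining from FDA Drug Labels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts medical-condition mentions (diseases, disorders,
    signs and symptoms) from the narrative sections of FDA Structured
    Product Labeling (SPL) drug labels. Parses a simplified SPL XML
    dialect, restricts to the eight LOINC-coded sections that carry
    medical-condition content, tags tokens with a linear-chain
    conditional random field over token, linguistic and semantic
    features, corrects boundaries with dictionary-based post-processing
    under a maximum-coverage rule, and assembles
    drug/condition/section-header triples. Includes token-level and
    four-criterion span-level evaluation (exact, left, right, partial
    match) with approximate-randomization significance testing, and a
    seeded synthetic-corpus generator for end-to-end testing without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
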
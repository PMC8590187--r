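Package: radterm
Title: Dictionary-Lookup Named Entity Recognition for Radiology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A dictionary-lookup named entity recognition (NER) toolkit for
    free-text radiology reports, centred on compound terms (multi-word noun
    phrases such as "right upper lobe") and their head ("stem") words.
    Provides pipe-separated (BSV) dictionary and ontology-table input/output
    with top-class ancestor tracing, noun-phrase chunking over a rule-based
    tagger, exhaustive suffix-pattern generation around stem terms,
    span-level precision/recall/F evaluation against standoff gold
    annotations, construction of a compound-terms-enhanced dictionary (CtED)
    from false-negative and false-positive analysis, stem-term occurrence-
    and matching-ratio analytics with ontology class profiling, and a
    seedable generator of toy ontologies, dictionaries and radiology-style
    corpora so the whole pipeline is testable without licensed data.
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
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
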
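Package: ontomine
Title: Ontology Synonym Enrichment and Concept Tagging for Patient Forum Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enriches a clinical ontology with patient-preferred synonyms mined
    from online patient-forum text by iterative tf-idf ranking with expert
    curation, and applies the enriched ontology to downstream analysis:
    dictionary-based concept tagging with per-forum class frequency tables,
    quantification of the post-count gain from added synonyms, chi-square forum
    comparisons, lexicon-based sentiment scoring with per-forum quartile
    retention, and screened, backward-eliminated logistic models of negative
    sentiment reporting odds ratios, information criteria, likelihood-ratio
    tests and AUC. Includes a seeded synthetic-forum generator so the whole
    pipeline is testable without access to the original fora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readr,
    dplyr,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml
Config/testthat/edition: 3
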
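Package: sievecid
Title: Chemical-Induced Disease Relation Extraction with Sieve-Based
    Coreference Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular pipeline for extracting chemical-induced disease (CID)
    relations from PubMed-style abstracts. Implements joint decoding of a
    structured-perceptron named-entity recognizer with a two-stage concept
    normalizer (supervised semantic indexing with a skip-gram embedding
    back-off), a nine-pass sieve coreference resolver that converts
    inter-sentence relations into intra-sentence candidates, a linear
    hinge-loss relation classifier over a large dependency-based feature
    set, and a five-step distant-supervision corpus builder driven by a
    curated chemical-disease relation table. Ships deterministic synthetic
    fixture generators (toy ontologies, annotated abstracts, parses,
    curated-relation tables) so the whole pipeline is testable at desk
    scale, plus PubTator, CoNLL-U and TSV readers/writers and
    BioCreative-style precision/recall/F1 evaluators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    igraph,
    jsonlite,
    SparseM,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
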
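Package: adrminer
Title: Ontology-Based Mining and Class-Effect Analysis of Adverse Drug
    Reactions from Drug Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dictionary- and rule-based tagging of adverse drug reaction
    (ADR) mentions in structured drug-label XML, with term-variant
    expansion (plural/singular forms, laboratory-test phrasings,
    abbreviation handling with an acronym guard), normalization of
    mentions to preferred terms, precision/recall evaluation against
    gold annotations, construction of thresholded ADR-ADR co-occurrence
    networks with degree and eigenvector centrality, and ontology-based
    drug class-effect analysis via the proportional class-level ratio
    (PCR) with hierarchical sub-ontology extraction of shared ADRs.
    Includes a deterministic synthetic-universe generator (dictionary,
    is-a ontology, labels with planted gold mentions, drug classes with
    planted class effects) for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    igraph,
    jsonlite,
    stringi,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
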
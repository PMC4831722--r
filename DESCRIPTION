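Package: cidre
Title: Chemical-Induced Disease Relation Extraction from Annotated Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dictionary-based disease named-entity recognition and
    normalization for PubTator-annotated Medline abstracts, and
    document-level extraction of chemical-induced disease relations.
    Disease mentions are recognized by greedy longest-match dictionary
    lookup with abbreviation propagation, span merging, exclusion-list
    filtering and MeSH normalization.  Candidate chemical-disease pairs
    are classified with a class-weighted RBF support vector machine over
    knowledge-graph path features, document-level statistical features
    and dependency-tree linguistic features (governing verbs, relating
    words, negation).  Includes micro-averaged evaluation, sentence
    co-occurrence and knowledge-base baselines, and a seeded generator
    of synthetic corpora with planted ground truth for hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
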
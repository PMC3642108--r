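Package: semsimval
Title: Semantic-Similarity Validation of Ontology-Mapped Entity Annotations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-filters named-entity identification results that have been
    mapped to a DAG-shaped ontology (such as ChEBI). Each mention is scored by
    its semantic similarity (Resnik, simUI or simGIC over intrinsic
    information content) to the other concepts co-mentioned in its text
    window; a threshold, absolute or fraction-based, partitions mentions into
    validated entities and outliers. Includes exact-match evaluation against a
    gold standard (precision, recall, true-positive ratio, precision
    increase, validation curves with a random-selection baseline) and a
    synthetic generator for toy ontologies and annotation corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, igraph, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
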
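Package: relcascade
Title: Cascading Entity-Relation Triple Extraction with Sequence-Labeling
    Noise Filtering and Radical-Word Feature Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint extraction of (subject, relation, object) triples from
    Chinese domain text, built for low-resource settings such as food
    health and safety monitoring.  The pipeline combines a BiLSTM-CRF
    sequence labeler over a modified BIO alphabet that separates
    domain-relevant ("Food") from distracting ("Noise") entities, semantic
    feature enrichment by decomposing characters into radicals and by
    fusing character-level with word-level representations, and a
    cascading binary pointer tagger that first marks candidate subjects
    and then, conditioned on each subject, marks objects separately for
    every relation so that overlapping triples can be recovered.  All
    neural components are small, seeded and trainable on a CPU; a
    synthetic toy-language corpus generator makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    stringi,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
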
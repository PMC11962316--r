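Package: medscalener
Title: Task-Oriented LLM Prompting for Medical-Scale Entity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes medical-scale entities (scale names, measurement
    concepts, measurement items) in Chinese medical text with a chat LLM:
    type-conditioned kNN demonstration retrieval over sentence embeddings,
    two-step chain-of-thought named entity recognition (entity-type
    recognition followed by marker-based labeling), and Yes/No
    self-verification of every extracted entity. Ships the corpus data
    model and JSON-Lines standoff I/O, corpus preparation (clue-word
    paragraph filtering, document-level splitting, training-pool
    subsampling), inter-annotator agreement, exact-string-match evaluation
    with a four-way error taxonomy, a synthetic corpus generator, and a
    deterministic gold-playback backend so the whole pipeline runs and is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    tibble,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
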
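Package: dmccda
Title: Double Matrix Completion for circRNA-Disease Association Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts circRNA-disease associations by double matrix
    completion (DMCCDA). Sequence (Levenshtein), disease-ontology semantic
    (Wang's method) and Gaussian interaction profile similarities are fused
    into two bounded-nuclear-norm matrix completion problems solved by
    ADMM singular-value thresholding, one in circRNA space and one in
    disease space, and the recovered score matrices are blended into a
    single ranking of candidate pairs. Includes leave-one-out and repeated
    five-fold cross-validation, a new-node protocol, a seeded synthetic
    instance generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    optparse,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
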
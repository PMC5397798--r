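Package: coreMSA
Title: Core Column Prediction and Coreness-Augmented Accuracy Estimation
    for Protein Multiple Sequence Alignments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts the coreness of columns in computed protein multiple
    sequence alignments. Columns are represented as profiles over joint
    (amino acid, secondary structure) states, grouped into windows of
    consecutive columns, and scored by class-specific metric distance
    functions learned through a large-scale linear program with target,
    impostor and triangle-inequality constraints. Nearest-neighbor distances
    to structured window classes are transformed into coreness values by
    fitted logistic curves. Predicted coreness feeds an alignment accuracy
    estimator (a non-negative linear combination of feature functions,
    several of them coreness-weighted) used for parameter advising: picking,
    among alternate alignments of the same proteins, the one of highest
    estimated accuracy. A synthetic benchmark generator produces reference
    alignments with annotated core columns, secondary-structure confidence
    tracks, and alternate alignments of controlled true accuracy, so the
    whole pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Matrix,
    Biostrings,
    pracma,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml
SystemRequirements: Python (>= 3.8) with numpy and scipy, available as
    'python' on the PATH (used to solve the distance-learning linear
    program through scipy's HiGHS interface).
Config/testthat/edition: 3
RoxygenNote: 7.3.3
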
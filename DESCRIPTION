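Package: sunrule
Title: Interval Rule Mining with a Parallel Sunflower Optimisation Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mines interpretable per-class interval rules
    ("if lo <= attr <= hi and ... then CLASS") from labelled numeric
    sensor tables using a parallel sunflower optimisation algorithm
    (SFOA). Candidate rules are encoded as continuous vectors
    (activation scores plus normalized lower/upper bounds), scored by
    confusion-matrix accuracy on the training partition, and mined
    per class in label-specific subspaces by independent optimiser
    islands. Includes exact min-max normalization with raw-unit
    round-trip, a planted-rule synthetic benchmark generator with
    label noise and null controls, repeated-experiment statistics
    (best/worst/mean/median/std of held-out accuracy), and a small
    command-line harness. Motivated by electronic-nose (MQ-series and
    related metal-oxide gas sensor) classification of bovine
    reproductive state, but generic over any numeric feature table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
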
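Package: CellTrackCGP
Title: Tracking, Motility Features and Evolved Classifiers for Monolayer
    Time-Lapse Videos
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing adherent cells in monolayer time-lapse
    microscopy. Implements distance-transform-based cell detection and
    frame-to-frame tracking, extraction of ten population-level motility and
    contact features (migration speed, migratory persistence, cohesivity,
    clump statistics), per-feature one-way ANOVA across treatment groups, and
    a Cartesian Genetic Programming (CGP) classifier evolved with a
    (1+lambda) strategy whose decision rule can be exported as a mathematical
    expression over the feature names. A synthetic-scene generator produces
    persistent-random-walk videos with ground-truth trajectories and contacts
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
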
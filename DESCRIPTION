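Package: locostate
Title: Locomotion-State Analysis of Cortical Calcium Imaging Sessions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-photon calcium imaging sessions
    recorded in head-fixed mice on a treadmill, built around the question of
    whether a neuromodulatory or neuronal signal encodes a binary locomotion
    state rather than a graded locomotion velocity. Provides percentile-filter
    drift correction to compute dF/F, polyphase resampling to a canonical
    frame rate, threshold-based locomotion onset/offset and bout detection,
    event-triggered response quantification (responsiveness classification,
    response latency, velocity tuning, binary-state versus linear-velocity
    model comparison), state-resolved mean pairwise correlation analysis, and
    a nested hierarchical bootstrap engine for inference on mouse/site/unit
    nested data. A seeded synthetic-session generator with full ground truth
    makes every stage testable by parameter recovery without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, TimeCourse, Preprocessing, StatisticalMethod
RoxygenNote: 7.3.3
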
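Package: ymazer
Title: Quantitative Analysis of Y-Maze Spontaneous Alternation from Pose Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for scoring spatial working memory in the Y-maze
    spontaneous alternation test from multi-body-point pose-tracking
    output. Reads DeepLabCut-dialect CSV tracks, aggregates body parts
    into head and tail-base points, projects positions onto normalized
    arm coordinates, derives the center-zone boundary from occupancy
    profiles, detects arm visits with a dual-point (head AND tail base)
    crossing rule, sweeps the arm-visit threshold to compute alternation
    rate, arm-choice bias and visit-sufficiency curves, simulates
    bias-matched chance-level alternation, computes recency-based memory
    statistics, and compares cohorts with a cluster-based permutation
    test. Includes a synthetic agent and trajectory generator so the
    entire pipeline can be validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
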
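Package: homecagedev
Title: Developmental Analysis of Long-Term Multi-Animal Home-Cage Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream analysis of continuous multi-animal home-cage
    tracking across rodent postnatal development: identity-switch detection
    and repair for pose-derived centroid tracks, gap interpolation, heuristic
    behavior classification (region-of-interest occupancy, open exploration,
    distance traveled, pairwise proximity, group socialization, approach
    detection, huddle attribution), adult-normalized developmental
    trajectories with Kolmogorov-Smirnov rapid-development detection, convex
    hull overlap of trajectories in principal-component space, social-state
    transition graphs on a discretized arena, and Bhattacharyya-distance
    changepoint detection for the emergence of circadian rhythms. Includes a
    stochastic family simulator with planted developmental structure and
    corruption injectors so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    rhdf5
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
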
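Package: effcomm
Title: Detecting Communicative Action Through Expectations of Efficient Movement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how observers recognise that a movement is
    communicative rather than directed at the physical world. Provides a
    generative space of 2-D motion trajectories chained from sixteen motion
    primitives, a path rarity statistic based on deviation from the shortest
    path, a Bayesian inverse-planning observer that scores how strongly a
    trajectory reveals the absence of a world-directed goal, a synthetic
    Likert-judgment generator for end-to-end testing, and the statistical
    pipeline (bootstrap correlations, permutation tests, linear calibration,
    per-class discrepancies) linking model scores to communicativeness
    judgments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
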
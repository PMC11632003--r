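Package: pupilphase
Title: Streaming Detection of Pupil Phase Events in Pupillometry Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects dilation, peak, constriction, and trough events in
    live or replayed monocular pupil-size streams using a four-stage
    streaming algorithm with adaptive, subject-specific percentile
    thresholds. Includes an offline replay simulator with human, mouse and
    monkey presets, a synthetic pupillary-unrest generator with analytic
    ground truth, post hoc ground-truth phase indices with accuracy,
    sensitivity and temporal-performance statistics, and event-locked
    epoch analysis with cluster-based permutation testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    zoo,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
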
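Package: capdyn
Title: Co-Activation Pattern Dynamics for Parcellated Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-wise co-activation pattern (CAP) analysis of parcellated
    resting-state fMRI time series. Pools individual BOLD frames across
    subjects and scanning sessions, clusters them with k-means under
    correlation distance, selects the number of brain states with a
    cluster-validity-index elbow criterion, and summarises each session's
    state sequence as fraction of time, mean dwell time, and transition
    probabilities on the duplicate-collapsed sequence. Includes the
    longitudinal and cross-sectional statistical layer used to compare a
    treatment group against healthy controls under Bonferroni test families,
    and a synthetic-cohort generator with known spatial states and Markov
    dynamics so the full pipeline is testable without access to restricted
    imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
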
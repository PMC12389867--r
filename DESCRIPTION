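Package: spemtrack
Title: Trajectory-Based Analysis of Smooth Pursuit Eye Movements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying smooth pursuit eye movements (SPEM) from
    screen-based eye-tracking recordings. Generates the five-stage
    bouncing-ball pursuit stimulus, resamples irregular gaze recordings to a
    uniform clock, and computes three trajectory-similarity indices:
    spatiotemporal colocality of lattice balls around target and gaze,
    circular direction-difference indices (per-sample mean resultant and
    per-segment regression-line orientation), and mean Shoelace polygon area
    over fixed-length windows. Includes group-level statistics
    (Lilliefors-type normality screening, Wilcoxon-Mann-Whitney, Hedges' g),
    a leave-one-out Gaussian-kernel SVM evaluation harness with grid search,
    permutation testing and bootstrap confidence intervals, and a synthetic
    gaze simulator with controllable tracking noise, lag and attentional
    lapses for end-to-end validation. Ships the per-subject index table of a
    9-patient / 9-control schizophrenia pursuit cohort as a packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071
Suggests:
    testthat (>= 3.0.0),
    nortest,
    jsonlite
Config/testthat/edition: 3
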
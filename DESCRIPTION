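Package: gazefix
Title: Velocity-Based Fixation Detection for Low- and High-Quality
    Eye-Tracking Data
Version: 0.1.0
Authors@R:
    person("gazefix", "developers", email = "gazefix@example.org",
           role = c("aut", "cre"))
Description: Parses raw binocular (or monocular) eye-tracking recordings
    into fixations using an adaptive velocity-threshold pipeline designed
    for variable-quality data such as infant recordings: binocular
    averaging and bilateral smoothing, gated interpolation of short
    missing-data gaps inside fixations, velocity-based segmentation, and
    three ordered post-hoc validation filters (merging of adjacent
    fixations, RMS-precision rejection, minimum-duration rejection).
    Includes recording-level data-quality metrics (RMS intersample
    precision, dispersion, data loss), per-fixation pupil means, a
    synthetic gaze simulator with ground-truth events for validation, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
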
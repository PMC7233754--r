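Package: cogstream
Title: Composable Neuropsychological Tasks with a Synthetic Consumer EEG Stream
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless pipeline for EEG-driven cognitive-neuropsychological
    experiments built around consumer-grade 14-channel headsets. Composes
    n-Back working-memory, eyes-open/closed and affective-valence task
    timelines; emulates a 128 Hz wireless EEG stream with state-modulated
    theta/alpha/beta/gamma oscillations over pink-noise background and known
    brain-behavior coupling; persists time-indexed signal and event points
    alongside relational participant/group/task metadata; and analyses
    sessions into per-electrode Welch band-power tables, signal-detection
    behavioral metrics and cohort rank/product-moment correlations, with
    parameter-recovery validation on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    signal,
    optparse
Config/testthat/edition: 3
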
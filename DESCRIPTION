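Package: concertphys
Title: Audience Psychophysiology from Wearable Respiration and Motion Sensors
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for audience psychophysiology in live music
    settings. Segments a chest-belt respiration wave into breath cycles and
    classifies each as quiet or disrupted (augmented, rapid "snuck", or held
    breaths); derives quantity of motion from three-axis core-body
    accelerometry via jerk magnitude and detects discrete movement jolts;
    aligns repeated performances of the same work by dynamic time warping of
    constant-Q spectrogram features and warps annotations and signal
    timestamps into a common timeline; and relates breath-phase onsets and
    jolts to annotated musical events with a circular-shift permutation null.
    Includes a synthetic-data generator with ground-truth ledgers so every
    stage is testable without concert recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
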
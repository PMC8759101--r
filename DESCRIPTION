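Package: gazevr
Title: Classification and Validation of Eye and Head Movements in Virtual Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing combined eye and head tracking recorded from
    eye-tracking head-mounted displays. Implements velocity-threshold saccade
    detection with a head-speed-scaled threshold, classification of
    intersaccadic intervals in 100 ms epochs into fixation, vestibulo-ocular
    reflex (VOR), smooth pursuit, head pursuit and smooth pursuit with
    compensatory VOR, and ray-cast ground-truth validation against known
    object positions in the virtual scene. Includes a synthetic session
    generator for a cued visual-discrimination paradigm (static and
    ego-motion conditions) that produces gaze recordings with per-sample
    kinematic ground truth, so every stage of the pipeline can be tested
    without access to recorded data.
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
    withr
Config/testthat/edition: 3
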
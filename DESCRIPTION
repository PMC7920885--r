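Package: handmotion
Title: Video-Based Bimanual Hand Motion Analysis for Surgical Skill Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sensor-free assessment of open-surgery technical skill from overhead
    video. Tracks two colour-coded surgical gloves (dominant and non-dominant
    hand) frame by frame via HSV colour segmentation and bounding-box centres,
    derives 1 Hz speed, acceleration and directional-change series per hand,
    and summarises bimanual coordination with the Shannon joint entropy of the
    two hands' kinematics. Also computes the eight observational procedure-
    timing metrics (total, idle, active, milestone and dissection times,
    instrument changes and use) from annotated event timelines, with censoring
    at a procedure time limit. A seeded synthetic-data generator produces
    videos, ground-truth tracks and event timelines with controllable skill
    structure so every stage is testable without real surgical footage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    png,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
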
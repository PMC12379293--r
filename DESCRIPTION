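Package: PulseTrains
Title: Detection and Classification of Porpoise Click Trains and Vessel
    Noise in Stereo Pulse-Event Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for passive acoustic monitoring with stereo ultrasonic
    pulse-event recorders that store per-pulse parameters (detection time,
    received sound pressure on two hydrophones, and their arrival-time
    difference) instead of waveforms. Implements a rule-based filter that
    segments raw pulse streams into candidate narrow-band high-frequency
    click trains (nine criteria on pulse intervals, sound-pressure ratio,
    arrival-time-difference stability and duration) and candidate vessel
    noise events (three criteria), a fixed acoustic feature set for
    candidate events, random-forest classification of candidates into
    regular clicks, buzzes and noise (or vessel and non-vessel noise),
    detection-rate and confusion-matrix performance metrics, and a seeded
    soundscape simulator (click trains, buzzes, vessel noise, snapping
    shrimp background) that provides ground-truth annotations for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
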
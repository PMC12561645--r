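Package: wristgait
Title: Gait Detection and Stride Length Estimation from Wrist-Worn Accelerometers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects walking bouts, initial-contact (heel-strike) events and
    stride length from triaxial wrist-worn accelerometer recordings sampled at
    100 Hz. Implements a battery of norm-based gait-sequence detectors, nine
    initial-contact detectors, and intensity-based step-length models
    (Weinberg, Kim, Bylemans families) including adaptive-RMS and
    foot-length-augmented variants. Ships a technical-validation framework
    (windowed confusion metrics, tolerance-based event matching, ICC(2,1),
    exponential-decay error trends, Bland-Altman tables) and a weighted
    performance-index ranking of algorithms, together with a seeded synthetic
    wrist-signal generator with exact ground truth for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
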
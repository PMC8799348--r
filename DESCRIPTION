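Package: fficaps
Title: Feature-Fusion Capsule Networks for Surface EMG Gesture Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies windowed multi-channel surface electromyography (sEMG)
    recordings into hand gestures with a feature-fusion capsule network.
    Continuous recordings are cut into overlapping analysis windows; fourteen
    classical time- and frequency-domain features per channel are fused with
    the raw signal (outer-product feature maps plus stacked signal segments)
    and fed to a capsule network with a multilevel convolution block, dynamic
    routing-by-agreement, a family of squash activations including e-Squash,
    and a margin loss.  The network forward and reverse passes are implemented
    in base R matrix algebra and trained with Adam.  A synthetic sEMG
    generator emulating gesture-specific channel envelopes, subject gain
    variability and electrode displacement makes every stage testable without
    access to proprietary recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
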
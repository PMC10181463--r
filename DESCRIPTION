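Package: eegcascade
Title: Hierarchical Random-Forest Classification of Motor and Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying real and imagined limb movements from
    multichannel or single-channel (FP1) EEG recordings sampled at 512 Hz.
    Implements trigger-synchronized segmentation of task protocols,
    Butterworth band-pass preprocessing, statistical-moment features
    (orders 1 to 10), per-machine greedy feature selection and grid
    search, and a three-level cascade of seven random-forest machines
    that splits the eight-class problem into binary decisions
    (body region, body side, real versus imagined movement).  Includes
    three evaluation frameworks probing within-recording, cross-session
    and cross-subject generalization, and a synthetic multi-subject EEG
    generator with class-dependent signal statistics for end-to-end
    testing when recordings are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
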
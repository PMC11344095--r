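Package: popdecode
Title: Population State-Space Decoding of Cortical Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the geometry of simultaneously recorded
    cortical neuron populations. Spike trains and stimulus logs are turned
    into continuous population activity (binning, sequential-response
    averaging, Gaussian smoothing), a principal-component state space is
    fitted to spontaneous (prestimulus) activity, and evoked activity is
    decoded in that space with repeated-split k-nearest-neighbour
    classification scored by macro F1 against shuffled-label nulls.
    Includes time-windowed decoding of stimulus identity, dimensionality
    versus temporal resolution curves, neuron-subsampling curves, a
    single-neuron control analysis, a small convolutional-network control
    classifier, effect-size statistics (Cohen's d, paired t), and a
    synthetic spike-data generator emulating a patterned tactile/visual
    stimulation experiment so the whole pipeline is testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    zoo,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
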
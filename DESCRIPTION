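Package: oscmeg
Title: Source-Space Oscillatory Power Analysis for Simulated MEG Attention Paradigms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying attentional modulation of
    cortical oscillatory power in source-localized magnetoencephalography
    (MEG). Provides a toy two-hemisphere cortical mesh with anatomical-style
    parcellation and a smooth synthetic lead field, a generator for
    multi-subject sessions of an auditory "what" versus "where" attention
    paradigm with planted condition-dependent alpha-band effects, a
    depth-weighted minimum-norm inverse operator with loose orientation
    constraint, sustained Hanning-taper spectral power and 3-cycle adaptive
    time-frequency estimation with evoked-response subtraction and decibel
    normalization, and nonparametric cluster-based randomization inference
    over the cortical sheet and over time-frequency bins, including recovery
    scoring of planted effects against simulation ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
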
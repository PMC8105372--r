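Package: inscal
Title: Infrared Neural Stimulation Calcium Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing two-photon GCaMP calcium-imaging recordings
    acquired during pulsed infrared neural stimulation (INS). Covers beam
    dosimetry for an obliquely incident multimode fiber (footprint ellipse,
    radiant exposure, water absorption and penetration depth, Gaussian
    fluence fields), normalisation of raw fluorescence to dF/F0 with a
    3-sigma responder criterion, energy-density dose-response aggregation
    with the accompanying statistics, spatial-extent analysis of recruited
    cells (field-of-view alignment, per-axis normal fits, central-ellipse
    membership), and a fully deterministic synthetic-experiment generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
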
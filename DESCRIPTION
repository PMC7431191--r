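Package: larvaquant
Title: Quantification of Larval Crawling Kinematics, Nascent-Transcript
    FISH Ratios and Muscle Phenotype Proportions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify Drosophila larval locomotion from
    spine-tracking tables (peristalsis-cycle segmentation by zero
    crossings of the spine-length derivative, stride length, stride
    duration and walking rate), to measure nascent-transcript
    intensity ratios from two-channel 3D fluorescence in situ
    hybridisation stacks (sum-slices projection, per-channel background
    thresholding, ROI-integrated col/nau ratio), and to tally muscle
    phenotype proportions with Wilson confidence intervals. Includes
    ground-truth-known synthetic data generators for all three data
    streams, genotype-level linear-model statistics and report
    rendering.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
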
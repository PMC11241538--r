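Package: ccia
Title: Coronary Contrast Intensity Analysis for Angiographic Stenosis Grading
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for grading coronary artery stenosis from contrast
    angiography image sequences by coronary contrast intensity analysis
    (CCIA), the ratio of contrast time-intensity areas under the curve
    between a stenotic region and an equal-sized proximal region.
    Includes Stewart-Hamilton indicator-dilution flow estimation,
    pressure-derived fractional flow reserve (FFR) as the reference
    index, ECG-gated template-matching stabilization of moving in vivo
    angiograms, an in-silico pulsatile-flow stenosis phantom that
    generates angiographic stacks with full ground truth, and a
    statistical validation pipeline for the published patient table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tiff,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
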
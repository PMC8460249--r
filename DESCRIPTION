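Package: glomtune
Title: Glomerular Calcium-Imaging Tuning and Correlation Analysis for
    Antennal-Lobe Local Interneurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-neuron glomerular calcium-imaging
    recordings of insect antennal-lobe local interneurons: region-of-interest
    trace extraction from label-masked image stacks, photobleaching correction
    by biexponential fits to blank-stimulus trials, relative fluorescence
    change (dF/F0) computation, odor tuning curves from 3-second response
    areas under the curve, pairwise Spearman correlation of glomerular tuning
    curves, and nonparametric group comparison (Kruskal-Wallis with Dunn post
    hoc tests).  Includes a calibrated generator of synthetic recordings that
    emulates the signal regimes of spiking (type I) and nonspiking (type II)
    local interneurons so every pipeline stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    data.table,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
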
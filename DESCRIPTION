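Package: dgephys
Title: Feature Extraction for Dentate Gyrus Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for cellular electrophysiology of the
    dentate gyrus: intrinsic membrane and firing properties from whole-cell
    current-clamp step protocols (resting potential by Gaussian histogram
    fit, phase-plane spike threshold, rheobase, input resistance),
    miniature EPSC detection and kinetics (10-90% rise time, monoexponential
    decay), high-density microelectrode-array field-response metrics
    (area-mean amplitude, input-output curves, propagation time, train
    depression), and evoked excitation/inhibition ratios from paired
    voltage-clamp trains. A synthetic-data generator produces every input
    class with known ground truth, so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
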
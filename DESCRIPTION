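Package: numsense
Title: Modelling the Development of Visual Number Sense with Generative Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying visual numerosity perception in silico: an
    orthogonal dot-array stimulus space (Numerosity, Size, Spacing), a
    dot-array renderer with empirical feature measurement, comparison-trial
    construction with ratio-bin oversampling, a synthetic observer and a
    probit choice model with a guessing factor, discrimination-vector
    projection and angle analysis, unsupervised deep belief networks trained
    by contrastive divergence with a frozen linear readout for the
    comparison task, and representational similarity analysis with
    Kendall tau-A relatedness tests and noise ceilings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
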
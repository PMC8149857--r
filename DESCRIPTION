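Package: qsperceptron
Title: Quorum-Sensing Consortium Perceptrons: Simulation and Weight Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative model of a bacterial perceptron built from
    quorum-sensing sender and receiver Escherichia coli consortia. Provides
    Hill-equation transfer functions for activator and repressor sender
    promoters and for the receiver activation function, least-squares fitting
    of dose-response tables, generators for binary and graded pattern sets
    with single-bit-flip noise, a forward model mapping input patterns through
    a signed promoter-strength weight vector to simulated receiver
    fluorescence, and a gradient-descent weight-learning algorithm with
    discrete weight levels and direct-search refinement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
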
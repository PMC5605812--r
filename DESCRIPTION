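Package: hkspeckle
Title: Homodyned-K Modeling and Assessment of Ultrasonic Speckle Statistics
Version: 0.1.0
Authors@R:
    person("Speckle", "Maintainers", email = "maintainers@hkspeckle.org",
           role = c("aut", "cre"))
Description: Tools for first-order statistical modeling of ultrasonic
    envelope (speckle) data. Implements the Rayleigh, Rician, K and
    homodyned-K amplitude distributions with numerically robust density
    evaluation, random samplers and the closed-form intensity
    signal-to-noise ratio of the homodyned-K model; maximum-likelihood
    fitting of all four models on raw amplitudes or gray-level histograms
    by a cyclic Newton-Raphson scheme with BIC model selection; synthetic
    three-dimensional scatterer phantoms whose spatial organization moves
    continuously from clustered to random to regular through
    gamma-distributed spacings mapped along a Hilbert space-filling curve;
    a linear convolution pulse-echo simulator producing envelope images;
    and an assessment pipeline that fits the competing models over a grid
    of phantom organizations and reports parameter meaning and
    goodness-of-fit summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    statmod,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
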
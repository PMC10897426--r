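Package: mitofluct
Title: Stochastic Modelling of Mitochondrial Membrane Potential
    Heterogeneity in Stem Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes flow-cytometry mitochondrial membrane potential
    (TMRM fluorescence) intensity distributions into univariate Gaussian
    mixture components fitted by expectation-maximization with BIC model
    selection, gates percentile-defined low and high membrane-potential
    subpopulations, and simulates mitochondrial activity dynamics through
    successive cell divisions under a three-outcome multiplicative
    fluctuation model with an activity floor. Provides simulation-based
    grid-search estimation of the activity fluctuation coefficient,
    quantification of how many divisions gated low-potential progeny need
    to regain the parental activity distribution, a synthetic-data
    generator with known ground truth for every stage, and a command-line
    interface over tabular flow-event files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
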
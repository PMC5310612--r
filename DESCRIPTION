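Package: eggdiscrim
Title: Decision-Rule Analysis of Avian Egg Rejection from Reflectance Spectra
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for testing how avian brood-parasite hosts decide to reject
    foreign eggs. Converts eggshell reflectance spectra into receptor quantum
    catches under a tetrachromatic receptor-noise-limited visual model,
    embeds stimuli in a perceptually uniform (just-noticeable-difference)
    chromaticity space, and derives signed colour-gradient predictors.
    Fits binomial psychometric models (logit, probit, complementary log-log)
    of rejection probability, locates decision thresholds at p = 0.5 with
    bootstrap uncertainty, compares single-threshold versus multiple-threshold
    decision rules by AICc evidence ratios, performs zero-method multimodel
    averaging over a relative-likelihood candidate set, and contrasts host
    discrimination abilities via subsample-resampled psychometric slopes with
    Monte-Carlo Kolmogorov-Smirnov and rank-sum tests. A synthetic-data module
    generates eggshell-like spectra along natural (blue-green to brown) and
    artificial (green to purple) colour gradients and simulates host responses
    under either decision rule, so the full pipeline is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
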
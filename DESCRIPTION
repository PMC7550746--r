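Package: exposband
Title: Multipollutant Exposure Profiling from Silicone Wristband Samplers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for personal multipollutant exposure data
    measured with silicone wristband passive samplers. Provides detection
    frequency screening of left-censored concentration matrices, batch-median
    standardization, repeated-measures reliability via intraclass correlation
    with bootstrap confidence intervals, chained-equation multiple imputation
    with Rubin-rules pooling for exposure-predictor regression, and discovery
    of multipollutant exposure profiles with batch self-organizing maps
    selected by a cluster-validity consensus. Includes a synthetic cohort
    generator with known ground truth (latent profiles, intraclass
    correlations, planted covariate effects) so every stage of the pipeline
    can be exercised and validated without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
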
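Package: pcmeval
Title: Rasch Partial Credit Model Evaluation for Polytomous Rating Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and psychometric evaluation of polytomous rating-scale
    instruments under the Rasch partial credit model. Item step parameters are
    estimated by conditional maximum likelihood via elementary symmetric
    functions; person locations by weighted (Warm) or maximum likelihood.
    The evaluation pipeline covers five areas: dimensionality (principal
    component analysis of model residuals and Q3 residual correlations),
    response-category functioning (threshold ordering), item fit
    (infit/outfit mean squares with subsample-averaged standardized
    statistics), invariance (differential item functioning with logit-size
    criteria and data-driven covariate splits), and targeting/reliability
    (test information, conditional person separation index, coverage).
    Ordinal sum scores can be converted to interval (logit) measures for any
    item subset. Ships configured for the Perceived Stress Scale (14-, 10-
    and 4-item versions with negative/positive wording subscales) together
    with a synthetic-data generator emulating that design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
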
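Package: trdcar
Title: Spatiotemporal Disparities in Tobacco Retailer Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying neighborhood-level disparities in tobacco
    retailer density (TRD, retailers per 1000 residents) across census tracts
    and over time. Provides tract preparation and dichotomization rules,
    descriptive disparity and equitable-decline summaries, and a marginal
    negative-binomial count model with a conditional-autoregressive (CAR)
    spatial and autoregressive (AR) temporal working correlation, fit by
    iterated estimating equations with Wald inference, rate ratios, and
    model-based group predictions. A synthetic-state generator with
    calibrated covariate prevalences, clustered licensing cities, and
    Gaussian-copula negative-binomial counts makes the full pipeline
    reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
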
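Package: circatime
Title: Predicting Circadian Time from Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains sparse predictors of circadian time from high-dimensional
    gene-expression profiles. Each gene's expression is modelled as a periodic
    smoothing spline of time on the unit circle, spline fits are discretized
    and scaled by their residual noise, and sparse principal components (L1
    penalized matrix decomposition) select a small set of informative genes.
    Time for a new sample is estimated by maximum likelihood of its component
    scores over the circle. Includes extensions for joint prediction from
    groups of samples taken a known time apart, ensembling of predictors by
    summed log-likelihood or circular mean, and personalized predictors
    trained under universal feature guidance, together with grouped
    cross-validation harnesses, circular error statistics, and a seeded
    generator of multi-individual, multi-study rhythmic expression cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mgcv,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
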
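Package: timereprod
Title: Time-Interval Reproduction Behavior and Neural Population Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing time-interval reproduction experiments in
    which a subject measures the duration of a stimulus and reproduces it by
    its own timed behavior. Provides a synthetic-data generator (task
    simulator with adaptive feedback, a shrinkage observer model, and
    stereotype timing neurons driving inhomogeneous Poisson spike trains),
    behavioral summary statistics (regression slope, coefficient of
    variation, bias), causal spike-density functions with time normalization
    and z-scoring, single-cell and population correlation batteries,
    center-of-mass temporal-scaling indices with bootstrapped
    Kolmogorov-Smirnov controls, demixed and conventional principal component
    analysis with stratified bootstrapping and trajectory metrics,
    response-type categorization from component scores, linear (Wiener
    filter) decoding of elapsed time, running-speed response functions with
    shuffle controls, and a pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
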
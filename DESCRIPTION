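Package: tvatoj
Title: Quantifying Visual Salience from Temporal-Order Judgments with TVA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify visual attention from temporal-order judgment
    (TOJ) experiments using the Theory of Visual Attention (TVA). Two stimuli
    race with exponential encoding latencies towards visual short-term memory;
    the closed-form probability that the probe is encoded first links stimulus
    onset asynchrony to the observed judgment counts. The package provides the
    closed-form psychometric function and a Monte-Carlo race simulator, a
    hierarchical Bayesian binomial model (fit with JAGS) that estimates
    attentional weights, processing rates and processing capacity at the
    participant and group level, posterior summaries (kernel-density modes,
    highest density intervals, condition contrasts, a temporal-expectation
    weight correction), posterior predictive checks, a classical logistic
    psychometric fit, and a synthetic-experiment generator for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
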
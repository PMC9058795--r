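Package: songplast
Title: Bayesian Random-Regression Analysis of Individual Plasticity in Birdsong
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying among-individual differences in behavioural
    plasticity of birdsong. Derives song-level traits (song length, maximum
    frequency, short-term complexity) from syllable tables via k-means syllable
    typing, fits Bayesian uni- and bivariate random-regression (reaction-norm)
    mixed models with social-context-specific random intercepts and slopes
    using a blocked Gibbs sampler with parameter-expanded or inverse-Wishart
    priors, summarises posteriors (credible intervals, probability of
    direction, covariance-to-correlation transforms, variance contrasts), and
    estimates the repeatability of reaction-norm slopes across repeated
    recordings with a two-step procedure. Includes a synthetic-data generator
    that emulates the field study design the models assume, so the whole
    pipeline is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp (>= 1.0.0),
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
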
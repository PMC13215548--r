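Package: mortsmooth
Title: Subnational Under-Five Mortality: Direct Estimation, Functional
    ANOVA and Bayesian Space-Time Smoothing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating and smoothing subnational under-five
    mortality rates (U5MR) from full-birth-history survey data. Includes a
    survey simulator that generates two-stage stratified cluster samples of
    birth histories from a known space-time mortality surface; design-weighted
    direct estimation of region-by-year U5MR via discrete age-band hazards
    with delete-one-cluster jackknife variances; penalized B-spline smoothing
    and one-way functional ANOVA with permutation-based pointwise and global
    inference on the resulting mortality curves; a Bayesian hierarchical
    space-time model (ICAR spatial and random-walk temporal priors, iid
    interaction) fitted by Gibbs sampling on the logit scale with known
    design-based variances; forecasting via the random-walk recursion; and
    model assessment by DIC, conditional predictive ordinates and variance
    decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    splines,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
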
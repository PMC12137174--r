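Package: halesae
Title: Small-Area Estimation of Healthy Life Expectancy by County and Race
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end small-area estimation pipeline for healthy life
    expectancy (HALE) by county, race and ethnicity, sex, age, and year.
    Includes a synthetic-data generator with known ground truth; hierarchical
    binomial prevalence models with intrinsic conditional autoregressive
    (ICAR) spatial, random-walk temporal and age, and exchangeable race
    random effects fit by Laplace-approximate maximum marginal likelihood
    with an aggregation-consistent likelihood for coarsely reported data;
    regression of cause-specific years-lived-with-disability (YLD) rates on
    mortality and indicator covariates with draw-splitting uncertainty
    propagation; multiplicative raking of county-level rates to state
    benchmarks; abridged life tables and Sullivan's method for HALE; and
    draw-based uncertainty summaries with significance rules, small-population
    masking, and county disparity statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
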
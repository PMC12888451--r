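Package: pahc
Title: District-Level Small-Area Estimation of Women's Problems in
    Accessing Healthcare
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating district-level prevalence of women's
    self-reported problems in accessing healthcare (affordability,
    proximity, permission, support/companionship) from nested survey
    microdata of the DHS/NFHS type. Fits a four-level random-intercept
    Bernoulli-logit model (women in clusters in districts in states) by
    Metropolis-within-Gibbs MCMC, converts posterior residuals into
    precision-weighted cluster probabilities and district averages,
    partitions random-intercept variance across levels, tabulates
    survey-weighted prevalence and all sixteen problem combinations with
    confidence intervals, classifies between-round district change into
    decile bins and improvement categories, and harmonizes cluster
    assignments across administrative-boundary vintages with a crosswalk.
    A synthetic-data generator emulates the nested two-round sampling
    design so the full pipeline is testable without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
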
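Package: defaunate
Title: Defaunation Indices and Bayesian Community Occupancy Models for
    Camera-Trap Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify defaunation of tropical mammal and bird
    communities from systematic camera-trap surveys. Implements the
    weighted defaunation index D(r,f) with equal, conservation-status,
    body-size and rank weights together with a functional-extinction
    classifier; hierarchical Bayesian community occupancy models with
    imperfect detection, station covariates (canopy closure, village
    density) and a survey-effort covariate on detection, fitted by a
    built-in Metropolis-within-Gibbs sampler; Monte-Carlo propagation of
    occupancy posteriors into an occupancy-based defaunation index; and
    a synthetic-data generator emulating a paired hunted/degraded
    landscape study design so the full pipeline can be exercised and
    validated without field data.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    coda,
    png,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
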
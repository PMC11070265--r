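Package: sidewaysmap
Title: Joint Species Distribution Modelling and Fine-Scale Biodiversity Mapping
Version: 0.1.0
Authors@R:
    person("HJA", "Mapping Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits a regularized joint species distribution model (multivariate
    probit with a Monte Carlo likelihood, an optional deep feature network, a
    low-rank species covariance and a spatial trend surface) to presence-absence
    community samples with remote-sensing covariates, tunes it by random search
    with k-fold cross-validation, and projects it across a landscape raster to
    map per-species occurrence probability, species richness, community
    composition (t-SNE ordination) and probabilistic (Poisson-binomial) site
    irreplaceability. Includes a synthetic landscape/community generator so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rtsne,
    FNN
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
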
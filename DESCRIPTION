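Package: mbtraj
Title: Longitudinal Microbiota Trajectories, Steady States and Source Attribution
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal analysis of gut microbiota time series in
    small closed cohorts: reference-community normalization of OTU trajectories,
    horizon-graph banding, Jensen-Shannon and UniFrac beta diversity with a
    bootstrap median-regression trend test, detection and validation of
    per-subject microbiota steady states by Ward clustering of Jensen-Shannon
    distances, Bayesian source tracking of state transitions with a collapsed
    Gibbs sampler, co-abundance group inference over steady-state profiles, and
    a seeded synthetic cohort generator with planted ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante,
    phyloseq,
    biomformat,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
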
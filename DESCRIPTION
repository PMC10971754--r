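Package: kelpnet
Title: Co-Occurrence Networks, Hub Taxa and Community Assembly for Kelp
    Seedbank Microbiomes
Version: 0.1.0
Authors@R:
    person("Kelp", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing shotgun-derived microbial abundance tables
    from giant kelp (Macrocystis pyrifera) gametophyte germplasm ("seedbank")
    cultures. Implements compositional co-occurrence network inference
    (centered log-ratio transform, Meinshausen-Buhlmann neighborhood
    selection with stability-based regularisation choice), per-network
    topology statistics and Kleinberg hub scoring over subsampled network
    ensembles, proportional-odds ordinal regression linking network topology
    to sporophyte biomass quantiles with exhaustive and stepwise AIC feature
    selection, and zeta-diversity decline modelling that classifies community
    assembly as niche-driven (power-law decline) versus stochastic
    (exponential decline). A synthetic-data module generates abundance
    tables, taxonomy, metadata and presence-absence site matrices with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
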
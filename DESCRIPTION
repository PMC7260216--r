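Package: reefdiv
Title: Trait-Dependent Diversification, Tip Rates and Trophic Transitions on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how ecological traits shape lineage
    diversification on time-calibrated phylogenies. Provides forward
    simulation of trees under multi-state birth-death processes with
    character change (recording the true character history), the DR
    (inverse equal-splits) tip speciation-rate statistic with median
    pooling across tree sets, a multi-state speciation-extinction (MuSSE)
    likelihood engine with maximum-likelihood fitting, slice-sampling
    MCMC and hidden-regime (HiSSE-style) state expansion, marginal
    ancestral-state reconstruction and ancestral-state-conditioned
    stochastic character mapping with transition counting, and a
    bootstrapped gradient-boosting protocol that attributes tip-rate
    variation to ecological and geographical predictors. An orchestrated
    pipeline reproduces the full workflow on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    geosphere,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
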
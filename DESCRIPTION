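Package: netspill
Title: Spatial Spillover Analysis for Cluster Randomized Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the spatial reanalysis of geographic cluster randomized
    trials with standardized-mortality-ratio outcomes, motivated by bed-net
    trials against child mortality. Provides exploratory spatial statistics on
    the cluster contiguity graph (join counts and Moran's I with Monte Carlo
    permutation inference), geographically weighted Poisson regression,
    Poisson SMR models with IID, intrinsic CAR, BYM and Gaussian-process
    random effects fitted by a Laplace/penalized-likelihood engine,
    distance-based spillover and interaction analyses with parametric
    bootstrapping, and a cluster-reallocation diagnostic that dilates one
    arm's cluster boundaries stepwise and tracks the refitted intervention
    effect. A synthetic-trial generator with Voronoi cluster geography makes
    every stage testable without access to the original trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
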
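Package: fluxscreen
Title: Expression-Constrained Metabolic Flux Screening
Version: 1.0.0
Authors@R:
    person("Flux", "Screen Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based analysis of case/control transcriptomes on a
    genome-scale metabolic network. Converts per-sample gene expression into
    Michaelis-Menten Vmax reaction bounds, runs flux variability analysis per
    sample, computes empirical-Bayes moderated differential flux statistics,
    scores pathway-level differential abundance against a size-matched
    subsampling null, screens all-against-all in-silico metabolite knockouts
    for agonist/antagonist metabolites via Metabolite Effective Scores, and
    contrasts paired pre/post-exertion metabolomics between patient groups.
    Includes a synthetic-data generator with recorded ground truth and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
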
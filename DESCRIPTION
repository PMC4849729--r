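Package: drugflow
Title: Drug-Centric Analysis of Drug Propagation Across Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a drug-centric view of drug development: birth-aligned
    accumulation of studies and diseases per drug with power-law fits and
    within-cohort quintile (momentum) analysis; a drug-centric disease
    taxonomy built from pairwise mutual information over adopted-drug sets
    and Ward hierarchical clustering with Newick export; and inference of a
    directed disease-to-disease drug-propagation network from adoption times
    under a right-censored exponential (Poisson communication) model, with
    closed-form pairwise and multi-source maximum-likelihood estimators,
    graph metrics and bootstrap timing comparisons. Includes a seeded
    simulator of drug cascades over a latent disease network that provides
    ground truth for parameter-recovery testing, and a file-based pipeline
    runner with reproducible manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
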
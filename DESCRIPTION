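Package: immunodyn
Title: Immune Feature Dynamics Modeling for Longitudinal Mass Cytometry
Version: 0.1.0
Authors@R:
    person("Packard", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to derive cell-type-resolved immune features (cell frequencies,
    basal intracellular signaling, and stimulation responses) from labeled mass
    cytometry event tables, parametrize their rates of change across two
    gestational time points, and identify outcome-discriminating features with an
    L1-penalized logistic model under repeated random holdout, stability-based
    model reduction via a piecewise-regression breakpoint, Spearman correlation
    network community analysis, and univariate and confounder statistics. Includes
    a ground-truthed synthetic cohort generator so every stage of the pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    Rtsne,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
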
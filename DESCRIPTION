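Package: netaging
Title: Longitudinal Functional Brain Network Analysis for Aging Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how functional brain network organization
    changes across the adult lifespan in longitudinal resting-state fMRI
    cohorts. Builds Fisher-z connectivity matrices from ROI time series,
    detects functional modules by repeated fine-tuned Louvain clustering
    with agreement-matrix consensus and resolution-parameter selection by
    normalized mutual information, computes a network segregation index
    over all modules or a reliable subset, derives density-thresholded
    global and nodal graph metrics, and fits linear mixed-effects aging
    trajectories with contrasts and false-discovery-rate control. A
    synthetic-cohort generator with planted modular structure, per-subject
    random effects, group-dependent aging slopes and dropout provides
    ground-truth data for validation, so the full pipeline can be
    exercised without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    lme4,
    Rcpp,
    jsonlite,
    yaml,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
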
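Package: dopaconn
Title: Striatal D2/3 Receptor Availability and Load-Dependent Cortical
    Network Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable, fully testable re-implementation of a multimodal
    PET/fMRI analysis linking striatal dopamine D2/3 receptor availability
    (PET non-displaceable binding potential, BP_ND) to working-memory
    load-dependent cortical network connectivity and task performance.
    Provides a seeded synthetic-cohort generator with planted effect
    structure (n-back block design, parcellated BOLD time series with
    condition-dependent covariance, trial-level behaviour, and simplified
    reference tissue model time-activity curves), penalized reaction time
    and d-prime behavioural metrics, condition-wise Fisher-z functional
    connectivity with per-edge load regression, Louvain modularity
    maximisation with consensus clustering for data-driven network
    detection, basis-function SRTM fitting of BP_ND, and an inferential
    layer with Spearman correlations, Meng's comparison of dependent
    correlations, repeated-measures ANOVA, and BCa-bootstrap causal
    mediation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
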
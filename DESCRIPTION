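Package: glipnet
Title: Temporal Lipidome-Growth Network Analysis for Longitudinal Infant Cohorts
Version: 0.1.0
Authors@R:
    person("ENID", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for linking a longitudinal plasma lipidome to infant growth
    faltering. Implements lipid feature quality-control filtering (mass accuracy,
    blank ratio, missingness, dilution-series linearity), signed weighted
    correlation networks with module detection and eigenlipid summaries,
    fixed-effects (within) panel regressions with FDR screening, latent-class
    linear mixed models of growth trajectories fitted by EM with spline bases,
    and panel vector autoregression estimated by first-difference and system GMM
    with forward orthogonal deviations, Andrews-Lu lag selection, Hansen
    overidentification tests, stability analysis, and extraction of a signed
    directed temporal (Granger-type) association network. A synthetic cohort
    generator with known ground truth supports parameter-recovery testing of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
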
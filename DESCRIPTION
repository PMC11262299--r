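Package: thermoperf
Title: Thermal Performance Curves and Metabolic Thermal Sensitivity for
    Ectotherms
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the thermal sensitivity of ectotherm
    physiology from laboratory trials. Builds thermal performance curves
    (TPCs) from maximum locomotor speeds measured across thermal
    treatments, using boundary-anchored nonlinear least squares over a
    catalog of unimodal curve families with small-sample AICc model
    selection, and extracts the derived thermal metrics (maximum
    performance, optimal temperature, 80% performance breadth, thermal
    safety margin, thermal tolerance breadth). Processes open-flow
    respirometry traces into rates of carbon dioxide production (VCO2)
    via the lowest stable window rule, summarises resting metabolic rate
    (RMR), and computes Q10 thermal sensitivity coefficients. Fits the
    standard candidate set of linear mixed models for log10 RMR against
    thermal treatment, body mass and sex with individual random
    intercepts, selecting by AICc, with conditional R2, mass-adjusted
    marginal means and rank-based group comparisons. A synthetic-data
    generator emulates the full trial design so every stage of the
    pipeline is testable without access to raw trial data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
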
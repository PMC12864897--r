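Package: slhs
Title: Sepsis Learning Health System Analytics and Stay-Level Sepsis Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a hospital sepsis learning
    health system on tabular electronic-health-record registries. Generates
    synthetic multi-ward registries with clinician-adjudicated sepsis events,
    computes SOFA, NEWS2 and Charlson scores, implements a six-level sepsis
    label logic (no infection through septic shock), builds 6-hour window
    grids with 7-day rolling features and sequence tensors, trains a stacked
    classifier (random forest plus a compact recurrent network, combined by a
    second-stage forest over six probability features) with a recall-floor
    calibrated decision threshold, evaluates it with per-class metrics, AUROC
    contrasts and Cohen's kappa, gates deployment champion-challenger style,
    and estimates before/after quality-of-care impact with covariate-adjusted
    odds ratios and propensity-matched time-to-antibiotics comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
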
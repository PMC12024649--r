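Package: gcsens
Title: Growth-Coupled Sensitivity of Gene Regulatory Switches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and data-analysis tools for growth-coupled sensitivity (GCS) of
    bistable gene regulatory switches. Implements growth-rate-aware reductions of four
    switch circuits (autoactivator, protease-coupled, two-component, lac operon),
    saddle-node phase diagrams and critical-concentration curves, Monod growth kinetics
    and the inverse-Monod criterion for concentration-dependent sugar preferences,
    Hill induction-curve fitting, a Bayesian errors-in-variables log-log slope
    estimator, plate-reader growth-curve and Miller/fluorimetry assay processing,
    single-cell lineage switch detection, and synthetic-data generators with
    ground-truth sidecars for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
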
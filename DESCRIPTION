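Package: masldcea
Title: Cost-Effectiveness and Diagnostic Triage Analysis for mpMRI in
    Suspected MASLD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trial-based health-economic and diagnostic-triage analysis for
    multiparametric MRI (mpMRI) in the management of suspected metabolic
    dysfunction-associated steatotic liver disease (MASLD). Converts
    per-patient healthcare resource-use records into multi-country costs
    (unit tariffs, health-CPI inflation, currency conversion), applies
    cT1/PDFF threshold rules for MASH risk stratification and
    biopsy-avoidance evaluation (sensitivity, specificity, PPV, NPV), and
    computes incremental cost-effectiveness (ICER per diagnosis and per
    QALY) with willingness-to-pay price-threshold inversion. A synthetic
    cohort generator reproduces the statistical structure of a
    multi-national randomised trial so that every stage of the pipeline is
    testable without access to patient-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
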
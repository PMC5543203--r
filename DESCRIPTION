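Package: ki67cta
Title: Ki-67 Clinical Trial Assay Scoring, Agreement and Outcome Validation
Version: 0.1.0
Authors@R:
    person("Assay", "Informatics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for developing and validating Ki-67 immunohistochemistry
    scoring workflows for neoadjuvant endocrine therapy monitoring in ER+
    breast cancer. Implements grid-based visual point counting (VPC), a
    transparent stand-in automated image-analysis pathway with area-of-interest
    selection and triage rules, a combined scoring standard operating
    procedure, PEPI-0 classification at the 2.7 percent and 10 percent
    cut-points, two-rater agreement statistics (percent positive/negative
    agreement with exact Clopper-Pearson intervals, Cohen's kappa,
    correlations, Bland-Altman), Kaplan-Meier and log-rank relapse-free
    survival analysis, ROC/Youden cut-point selection, and a synthetic-data
    generator (cell maps, rendered fields, cohorts, paired rater scores) so
    the full validation pipeline is exercisable end to end without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
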
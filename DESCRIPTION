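Package: comorbscreen
Title: Density-Estimation Screening and Clustering of Co-Morbidity Structure
    in Matched Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage density-estimation analysis of co-morbidity structure
    in matched case-control cohorts built from administrative claims data.
    Stage one fits relaxed variable kernel density estimates (one isotropic
    Gaussian per subject with a k-nearest-neighbour bandwidth) to the
    medication-exposure feature vectors of cases and controls and flags
    "cases of interest" whose case/control likelihood ratio exceeds a
    threshold.  Stage two reduces the exposure features by factor analysis
    (Kaiser-Meyer-Olkin and Bartlett adequacy checks, eigenvalue-above-one
    retention, orthogonal rotation, loading cutoff) and clusters the screened
    cases with a compact mixture of weighted full-covariance Gaussian
    components fitted by expectation-maximization.  Includes a synthetic
    matched-cohort generator with planted exposure subpopulations and
    outcome odds ratios, and stratified 2x2 odds-ratio / chi-square / t-test
    machinery for demographics and co-morbidity tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
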
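Package: tivadj
Title: Head-Size and Age Adjustment of Regional Brain Volumes for
    Single-Subject Normative Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits normative models of regional brain volumes (brain
    parenchyma, thalamus, hippocampus) against total intracranial volume
    (TIV) and age in a reference database and converts individual
    deviations to z-scores, implementing and contrasting the residual
    method (ordinary least-squares adjustment with quadratic age and
    TIV-by-age interaction terms) with the proportion method (volume
    scaled to TIV, then age-adjusted). Includes outlier-robust two-pass
    regression with Tukey fences, a moment-matched synthetic cohort
    generator calibrated to published normative moments, per-subject
    z-score difference diagnostics, coefficient-of-variation and
    nuisance-correlation reporting, and rank-based ROC analysis of
    atrophy detection in a patient cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
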
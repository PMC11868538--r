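Package: ptaustage
Title: Biological PET Staging of Alzheimer's Disease with Plasma p217+tau
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns the 2024 Revised Criteria biological PET stages of
    Alzheimer's disease (Initial, Early, Intermediate, Advanced) from amyloid
    PET Centiloid values and tau PET SUVR in mesial-temporal, temporo-parietal
    and rest-of-neocortex composite regions, and evaluates how well a plasma
    biomarker (p217+tau, fg/ml) discriminates those stages. Provides empirical
    ROC curves with Mann-Whitney AUC, DeLong tests for paired AUC comparison,
    Youden and fixed sensitivity/specificity operating points with stratified
    bootstrap confidence intervals, two-threshold triage zoning, two-step
    screening, covariate-augmented logistic risk models, one-vs-rest logistic
    stage-probability curves with argmax crossover points, a sliding-window
    band estimator, Kruskal-Wallis/Dunn stage comparisons, and a synthetic
    cohort generator parameterised by published per-stage summary statistics
    so the full pipeline can be exercised without access to the original
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
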
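Package: fuzzyfda
Title: Fuzzy k-Medoids Clustering of Longitudinal Symptom Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for clustering noisy longitudinal mobile-health symptom
    diaries as functional data. Daily allergic-rhinoconjunctivitis records
    are scored with the combined symptom and medication score (CSMS),
    filtered and imputed, smoothed with roughness-penalized B-splines whose
    knots, order and smoothing parameter are selected by a total
    generalized cross-validation grid search, and clustered on the spline
    coefficients with a fuzzy k-medoids algorithm (a fuzzy k-means variant
    is included). Cluster validity is assessed with the fuzzy silhouette
    index, and patient curves are related to pollen-exposure curves through
    a permutation Spearman correlation test summarised as a per-patient
    allergy-pollen association index. A synthetic-cohort generator with
    known cluster structure supports method evaluation end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils,
    pracma,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
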
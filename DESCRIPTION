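Package: eaccd
Title: Ensemble Clustering of Survival Curves for Prognostic Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds data-driven prognostic staging systems from registry-style
    survival cohorts using the Ensemble Algorithm for Clustering Cancer Data
    (EACCD). Patients are grouped into factor-level combinations (e.g. TNM
    cells), pairwise survival differences are measured with a Gehan-Wilcoxon
    effect size, an ensemble of partitioning-around-medoids runs learns a
    consensus dissimilarity, and a minimax-linkage dendrogram is cut at the
    knee of the Harrell C-index curve to yield ordered prognostic groups with
    Kaplan-Meier curves. Includes a rule-based AJCC TNM stage comparator and a
    synthetic cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
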
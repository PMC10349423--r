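Package: timmrd
Title: Tumor-Informed Methylation-Based Minimal Residual Disease Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deconvolves targeted bisulfite-sequencing methylation counts from
    plasma cell-free DNA into circulating-tumor, adjacent-normal and background
    fractions under a mixed beta-binomial likelihood, scores each sample with a
    Wald statistic for the null hypothesis of zero tumor fraction (the
    timMRD-score), and evaluates longitudinal postoperative surveillance
    (lead times, horizon confusion matrices, ROC). Includes fitting of
    per-block beta background priors from healthy plasma, cohort and
    patient-specific differentially methylated block selection, a seeded
    synthetic-cohort generator emulating the assumed generative model, and
    export of survival-ready tables for standard survival tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp
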
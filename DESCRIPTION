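Package: metdysreg
Title: Metabolic Dysregulation Scoring and Recurrence Kinetics for Prostate Cancer Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying metabolic pathway dysregulation from
    tumor-versus-normal expression data and relating it to disease recurrence.
    Implements scale (TMM) normalization, log-CPM transformation and an
    empirical-Bayes moderated t-test; signed and absolute gene dysregulation
    scores with square-root-n pathway aggregation and cross-cohort ranking;
    normal-relative z-score patient scoring with quartile stratification,
    Kaplan-Meier estimation and log-rank testing of biochemical recurrence;
    a delta-beta differential DNA methylation caller with hypergeometric
    set-overlap testing, over-representation enrichment and overlap-network
    export; classification of xenograft tumor-volume trajectories into
    recurrence, stable-disease and complete-regression outcomes with interval
    status summaries and supporting exact and t-based tests; and seeded
    synthetic-data generators with ground-truth tables for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    fgsea,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
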
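Package: hemilat
Title: Hemispheric Laterality Analysis of Stress-Induced Gene Expression
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for hemisphere-paired transcriptome studies of
    chronic social defeat stress. Classifies mice into susceptible and
    resilient cohorts from sociability-index behavior, normalizes bilateral
    expression matrices with a detection-p filter, fits per-gene cell-means
    linear models with empirical-Bayes variance moderation and
    Benjamini-Hochberg FDR control across seven pairwise contrasts, scores
    and ranks per-gene hemispheric laterality (log2 L/R), tests gene-set
    lateralization of fold changes, and provides the accompanying behavioral
    statistics battery (t, Mann-Whitney, Kruskal-Wallis, two-way and
    repeated-measures ANOVA with Holm-Sidak post hoc). Includes a synthetic
    cohort generator with planted lateral effects and ground-truth tables so
    every stage is verifiable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    limma,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
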
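Package: contagion3d
Title: Quantifying Emotional Contagion to Faces in a Three-Dimensional
    Affective Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify emotional contagion from an induced affective
    state to judgments of facial expressions. Affective states are points in a
    three-dimensional monopolar space (negativity, positivity, arousal, each
    rated 0-100); contagion is one minus the Euclidean distance between the
    induced state and a face judgment, rescaled to [0, 1]. The package provides
    the contagion statistic, readers/writers and validators for long and wide
    rating CSVs, a seeded synthetic-cohort generator with a tunable assimilation
    effect, boxplot (Tukey-fence) outlier screening, the 2x2 split-plot ANOVA
    with partial eta squared, assumption checks (Shapiro-Wilk, Brown-Forsythe),
    Bonferroni-corrected paired t-tests, Pearson correlations with questionnaire
    totals, a likelihood-ratio test for a gender effect via nested mixed
    models, and a reproducible end-to-end pipeline with JSON/markdown reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
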
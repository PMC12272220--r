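Package: homolat
Title: Homotopic Functional Connectivity and Lateralized Intrahemispheric
    Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measurement and statistical modelling of interhemispheric
    homotopic functional connectivity (HoFC) and the laterality index (LI)
    of intrahemispheric functional integration from parcellated BOLD time
    series. Provides time-series post-processing (detrending, Friston-24
    nuisance regression, Butterworth band-pass filtering, task-event
    regression and background-connectivity estimation), construction of
    Fisher-z functional connectivity matrices and per-pair HoFC/LI
    measures, test-retest reliability (pattern similarity and ICC(2,1)),
    across-subject association statistics (partial correlation, Welch
    ANOVA with Games-Howell post hoc tests, GLM age effects), permutation-
    tested canonical correlation analysis against cognitive measures,
    pedigree-kinship variance-component heritability and genetic
    correlation, and between-subject and two-condition within-participant
    bootstrap mediation models. A synthetic-cohort generator with known
    ground truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
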
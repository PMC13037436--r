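Package: gutrhythm
Title: Diurnal Rhythmicity, Temporal Volatility and Sleep Maturation in
    Longitudinal Infant Gut Microbiota Cohorts
Version: 0.1.0
Authors@R:
    person("gutrhythm", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for linking the temporal structure of the infant gut
    microbiota to sleep maturation in densely sampled longitudinal cohorts.
    Implements fixed-period (24 h) cosinor fits of alpha diversity and genus
    relative abundance, a centroid-based temporal volatility statistic on
    principal-coordinate embeddings of beta diversity, bootstrap-averaged
    rarefied alpha and beta diversity (including Faith phylogenetic diversity
    and UniFrac), nonparametric rest-activity metrics from actimetry
    (interdaily stability, intradaily variability, relative amplitude and the
    Circadian Function Index), a composite infant sleep-quality score from
    questionnaire variables, diary-derived sleep and feeding history
    covariates, and a registry of random-intercept linear mixed models tying
    the pieces together. A fully seeded synthetic-cohort generator emulates
    the data layout so that every stage is testable end to end without
    access to restricted cohort metadata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    digest,
    jsonlite,
    lme4,
    Matrix,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
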
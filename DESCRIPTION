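Package: nocistat
Title: Phase-Wise Nociception Scoring, Parallel-Line Potency and Mast-Cell
    Degranulation Statistics for the Orofacial Formalin Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-drug antinociception interaction
    studies in the rat orofacial formalin test. Aggregates 3-minute
    face-rubbing bins into the biphasic phase totals, computes
    antinociceptive activity (AA%) against the concurrent vehicle group and
    percent inhibition (%I) of one drug's effect by an adjuvant, fits log
    dose-response lines, estimates Emax for submaximal-efficacy drugs by the
    double-reciprocal method and derives ED50s, compares alone versus
    combination curves by a parallelism F-test and the relative potency test
    with Fieller confidence limits, classifies the interaction (synergy,
    additive, antagonism), summarises mast-cell degranulation
    histomorphometry (high-representative-field averaging, degranulation
    inhibition I%, degranulation-pain Pearson correlation), and provides
    repeated-measures ANOVA with Tukey HSD post hoc comparisons. A seeded
    synthetic-data generator emulates the study's per-rat behavioral time
    courses and mast-cell fields so every stage is testable without animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
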
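Package: mirrorscreen
Title: Post-Trauma Self-Help Screening with the MIRROR Instrument
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the MIRROR (Mobile Insight in Risk, Resilience, and
    Online Referral) post-trauma self-help screening instrument: item
    validation and scale scoring, the severity x functioning x time triage
    algorithm with its green/orange/red outcome and advice composition, and
    scoring of the reference instruments used to validate it (PCL-5, DASS-21,
    RES, MHC-SF). Also provides the psychometric evaluation pipeline for
    ordinal questionnaire data: polychoric correlations, exploratory factor
    analysis with oblique geomin rotation, confirmatory factor analysis fit
    indices (CFI, TLI, RMSEA) with nested-model comparison, Cronbach alpha and
    item-total reliability, Welch ANOVA with Games-Howell post hoc tests, and
    a seeded synthetic-cohort generator with a two-factor latent structure for
    end-to-end testing without respondent data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tools,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
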
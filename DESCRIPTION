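Package: hemilat
Title: Hemispheric Lateralization of Resting-State Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes hemispheric laterality indices from resting-state
    functional connectivity between homotopic cortical vertex pairs.
    Implements Fisher-z connectivity matrices, per-vertex intrahemispheric
    and interhemispheric-heterotopic strength sums, pair-wise laterality
    indices LI = (L-R)/|L+R|, network-restricted averaging, cosine
    alignment of individual lateralization maps to a young-group template,
    and the accompanying inferential battery (Welch and classic one-way
    ANOVA with Games-Howell or FDR-corrected post hocs,
    Jonckheere-Terpstra trend tests, partial correlations with covariate
    residualization). A synthetic-cohort generator with a factor-model
    covariance plants known lateralization and brain-behavior links so
    every stage is verifiable without imaging data; psychometric utilities
    fit logistic speech-reception thresholds and score digit-span and
    Stroop tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
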
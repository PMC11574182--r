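Package: cohortpe
Title: Bayesian Cohort Simulations of Prediction Error and Sharpened Signals
    in Spoken Word Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates incremental Bayesian lexical inference over a
    frequency-weighted lexicon and derives two competing readouts of how
    predictions combine with speech input: sharpened signals (prediction
    multiplied with sensory evidence) and prediction errors (evidence minus
    prediction). Provides the stimulus-design statistics (conditional syllable
    probability, surprisal, entropy), representational similarity analysis
    tools (Euclidean and cross-validated Mahalanobis pattern distances,
    normalised Levenshtein phonetic dissimilarity, reciprocal-pair exclusion,
    Fisher-transformed Spearman RDM correlations), group-level sensor
    statistics (sensor selection, RMS time courses, epoch outlier rejection,
    cluster-based sign-flip permutation tests, within-subject standard
    errors), and a synthetic-data generator that emulates the Strong/Weak x
    Match/Mismatch cross-splicing design so the whole pipeline can be
    exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
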
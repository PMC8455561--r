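Package: erpvote
Title: EEG Decoding and Behavioral Statistics for Pre-Electoral Attitude Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested analysis chain for pre-electoral EEG studies of political
    attitudes: a synthetic-data generator emulating epoched multichannel EEG
    around survey-item critical words, deterministic preprocessing with
    exclusion bookkeeping, N400 congruency analysis with mixed-design ANOVA
    (Greenhouse-Geisser correction, partial eta squared), sliding-window
    multivariate decoding of populist versus non-populist survey items with
    empirical shuffled-label chance and cluster-mass permutation statistics,
    a Kelley-style self-report index, Implicit Association Test D-scoring
    with split-half reliability, and a six-model logistic comparison of
    implicit and explicit predictors of voting choice (McFadden and
    Nagelkerke pseudo-R-squared, lambda proportional reduction in error,
    Wald coefficient-equality tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
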
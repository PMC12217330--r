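Package: levospeech
Title: Digital Speech Biomarkers of Acute Levodopa Response in Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying acute dopaminergic medication effects on speech in
    Parkinson's disease from three standard speech tasks (sustained phonation,
    /pa/-/ta/-/ka/ syllable repetition, and passage reading). Implements extraction of
    16 digital speech biomarkers (pitch and intensity prosody, speech timing, voice
    onset time, harmonics-to-noise ratio, maximal phonation time, and four long-term
    average spectrum moments), normality-routed paired OFF/ON statistics with
    Holm-Bonferroni correction, covariate-adjusted contrasts against healthy controls,
    backward stepwise AIC regression of hypokinetic and hyperkinetic symptom change,
    proportional marginal variance decomposition (pmvd) and LMG relative importance,
    weighted z-scored compound speech scores, leave-one-out cross-validated evaluation,
    and a randomized medication-state-transition classifier. Because patient recordings
    of this kind cannot be shared, the package includes a ground-truthed synthetic audio
    and cohort generator so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    tibble,
    dplyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
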
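Package: emovar
Title: Momentary Emotion Differentiation and Emotion Regulation
    Variability in Experience-Sampling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for within-person analysis of intensive longitudinal
    (experience sampling, ESM) emotion data. Computes momentary emotion
    differentiation (an assessment-level decomposition of the average-measures
    consistency intraclass correlation), momentary emotion regulation
    variability as Bray-Curtis dissimilarity with its additive partition into
    strategy-switching (balanced variation) and endorsement-change (abundance
    gradient) subcomponents, person-mean centering and lag alignment, lagged
    multilevel cross-lag models with AR(1) residuals and equivalence (TOST)
    testing, and stacked 1-1-1 within-person mediation with a Monte-Carlo
    confidence interval for the indirect effect that includes the covariance
    of the person-specific paths. Includes synthetic ESM data generators with
    known ground truth for estimator validation and end-to-end pipeline tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    nlme,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
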
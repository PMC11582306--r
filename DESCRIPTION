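Package: rrbias
Title: Randomized-Response Prevalence Estimation with Evasive-Response-Bias Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the design and analysis of randomized-response (RR) surveys on
    sensitive attributes, with explicit correction for evasive response bias. Builds
    misclassification transition matrices for the classic single-question, sub-samples,
    multiple-questions and ever/last-year RR designs; fits null, cheater-detection (CDM),
    self-protective-no (SP-no) and SP(last-year) models by multinomial maximum likelihood
    with a softmax parameterization; reports delta-method standard errors, deviance (G2)
    goodness of fit and AIC; and provides a respondent-level simulator, Monte-Carlo power
    analysis for detecting evasive responding, and the observed frequency tables of two
    Dutch doping surveys as bundled fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
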
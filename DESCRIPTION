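Package: vadesign
Title: Nonparametric Cause-Specific Mortality Fraction Estimation from
    Verbal Autopsy Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the distribution of deaths across causes (the
    cause-specific mortality fraction, CSMF) in a community from verbal
    autopsy symptom surveys, using a nonparametric back-calculation that
    solves P(S) = P(S|D) P(D) by simplex-constrained least squares
    averaged over random symptom subsets.  Includes stratified adjustment
    for known compositional differences between the hospital training
    sample and the community, Bayes-rule classification of individual
    deaths, an iterative residual-t procedure with Bonferroni correction
    for detecting symptom questions that are reported differently in the
    two samples, a synthetic-data generator for cause-conditional
    Bernoulli symptom models with configurable misreporting, and scripted
    Monte-Carlo design experiments (sensitivity irrelevance, bias
    detection, efficiency grids).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
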
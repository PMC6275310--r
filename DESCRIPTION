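Package: scmnet
Title: Perception Accuracy and Transitivity in Classroom Affiliative
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Social Cognitive Map (SCM) peer-group
    nomination data. Reads classroom rosters and group-listing reports,
    expands listed groups into perceived affiliative networks, derives the
    consensus ("true") network by the dyadic intersection rule, scores
    each perceiver's precision, coverage and accuracy index, computes
    classroom transitivity from triangle and two-path counts, and fits
    longitudinal random-intercept models relating between- and
    within-person transitivity to perception accuracy. Includes a
    synthetic-study generator with controllable transitivity and report
    noise for calibration and recovery testing.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
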
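Package: aidiet
Title: Anti-Inflammatory Diet Score and Case-Control Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for an item-based anti-inflammatory diet score derived from
    seven-point food-frequency questionnaire data, PCR-RFLP genotype calling
    for the COX-2 promoter -765G>C polymorphism, and the complete case-control
    association analysis around them: contingency tables, crude odds ratios
    with Woolf confidence intervals, multivariate logistic regression with
    Wald trend tests, likelihood-ratio tests for covariate retention and
    gene-environment interaction, and genotype-stratified estimates. A
    calibrated synthetic-data generator emulates a frequency-matched melanoma
    case-control study so the whole pipeline runs at desk scale without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
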
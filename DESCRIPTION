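Package: comorbnet
Title: Multimorbidity Co-Occurrence Networks and Emotional Distress in
    EMR Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for multimorbidity patterns and their
    association with clinically significant anxiety and depression (CSAD)
    in hospital electronic-medical-record cohorts, calibrated to a large
    inpatient osteoporosis cohort. Provides a Gaussian-copula synthetic
    cohort generator with exact marginal prevalence control and planted
    pairwise disease associations; ICD-10 three-character normalization,
    multimorbidity counting and CSAD flagging; descriptive group
    comparisons (t and chi-square tests); multivariable logistic
    regression with Wald odds-ratio intervals; all-pairs observed/expected
    (O/E) relative-risk statistics; construction of comorbidity networks
    (including a CSAD pseudo-node network) with prevalence and relative-
    risk filters; and GEXF 1.3 / GraphML export for Gephi and general
    graph tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
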
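Package: eoscompare
Title: Comparing Management Strategies for Neonatal Early-Onset Sepsis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare two bedside strategies for managing neonates
    at risk of early-onset sepsis (EOS): the Bayesian neonatal sepsis risk
    calculator, which converts a maternal-risk prior into a posterior risk
    via clinical-presentation likelihood ratios, and an updated serial
    clinical observation protocol based on scheduled structured
    examinations with minor/major symptom grading and escalation rules.
    Includes a seeded synthetic cohort generator calibrated to published
    risk-factor prevalences and symptom-onset timing, paired-proportion
    statistics (exact and asymptotic McNemar tests, paired differences
    with Wald and Newcombe intervals), stratified rate summaries, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
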
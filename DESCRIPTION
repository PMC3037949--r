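Package: patternsim
Title: Stochastic Simulation of Diagnostic Errors in Chinese Medicine
    Pattern Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying misdiagnosis and undiagnosis caused by
    pattern similarity in Chinese medicine pattern differentiation.
    Provides a validated data model for Zangfu single-pattern datasets
    organised by the Four Examinations (inspection, auscultation and
    olfaction, inquiry, palpation), a seedable synthetic dataset
    generator, Monte Carlo simulation of true-positive case and
    true-negative control manifestation profiles, a rule-based pattern
    differentiation algorithm scored on explained and available
    information, Jaccard-based dual-pattern and pattern-dataset
    similarity measures with ordinal categorisation, Goodman-Kruskal
    gamma ordinal association statistics, and an orchestrated study
    pipeline that runs the full simulation design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
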
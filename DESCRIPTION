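Package: trapdiff
Title: Differential Translatome Analysis with Additive P-Value Combination
    and Rescue Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for TRAP-Seq (translating ribosome affinity
    purification) translatome profiling of a 4-genotype x 3-treatment
    factorial design. Provides a negative-binomial Wald test for two-group
    contrasts with median-of-ratios normalization and trended dispersion
    shrinkage, additive (Edgington) combination of p-values across contrasts
    with both the truncated power formula and the exact Irwin-Hall
    distribution, rule-based classification of transcripts into basal,
    rescued and ICD-effect categories, a seeded negative-binomial count
    simulator with planted gene classes for ground-truth validation, and
    generic set-overlap partitioning plus hypergeometric over-representation
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
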
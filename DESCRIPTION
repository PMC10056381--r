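Package: domrisk
Title: Prevalence, Diagnosis and Offspring-Group Aggregation for
    Dominant-Allele Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative framework for single-gene diseases caused by a
    dominant allele under Hardy-Weinberg equilibrium: closed-form disease
    prevalence as a function of allele frequency and genotype penetrance,
    with envelope bounds and curvature classification; 2x2 diagnostic-table
    analytics with necessity/sufficiency classification, disease-iceberg
    correction and an interval estimator of prevalence from a test with a
    bounded false-positive rate; discrete age-of-detection rate curves and
    cumulative lifetime-risk analysis with truncation diagnostics; the six
    offspring-groups defined by parental genotypes, their recurrence-risk
    ratios and the proportion decomposition of diseased individuals,
    including the sibling recurrence-risk ratio identity lambda_s = 1; and a
    forward Mendelian family simulator with estimators and
    ascertainment-bias experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
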
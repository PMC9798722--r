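Package: metamarker
Title: Multi-Cohort Biomarker Evaluation by Effect-Size and Diagnostic
    Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Evaluates a candidate gene biomarker across many independent
    expression cohorts: standardized-mean-difference meta-analysis with
    DerSimonian-Laird random-effects pooling, heterogeneity and
    publication-bias (Begg) diagnostics, diagnostic-accuracy meta-analysis
    (pooled sensitivity/specificity, Moses-Littenberg sROC, Fagan nomogram),
    vote-counted differential-expression and co-expression screening with
    SMD confirmation, immunoreactivity scoring of immunohistochemistry,
    Fisher-z pooling of correlation coefficients, median-split survival
    analysis, degree-based hub-gene ranking and hypergeometric
    over-representation analysis. Includes a seeded synthetic multi-cohort
    generator with known ground truth for validating the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    metafor,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
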
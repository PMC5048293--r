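Package: exprest
Title: Seed-Guided Expression Signatures of REST Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives an expression-based signature of REST (RE1-silencing
    transcription factor) activity by correlating every gene against a seed
    gene across two cohorts and keeping sign-consistent, strongly correlated
    genes; scores samples as the mean expression of positively correlated
    (REST-type) genes minus the mean of negatively correlated (RESTless-type)
    genes; and ties the resulting score to molecular and clinical features
    through Spearman scans with beta-uniform-mixture FDR estimation, t tests,
    ANOVA with Tukey HSD, Fisher and Kolmogorov-Smirnov enrichment tests,
    drug-sensitivity fold changes, Kaplan-Meier curves, log-rank tests and
    Cox proportional-hazards models. Includes a synthetic-cohort generator
    with a known latent activity factor so every stage can be validated
    against planted ground truth, plus readers and writers for the tabular
    formats involved (TSV and GCT expression matrices, GMT gene sets,
    clinical tables, signature tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
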
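Package: panmethnet
Title: Pan-Cancer Expression, Methylation, Protein and Survival Profiling of
    Small Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for multi-cohort analysis of a small gene
    network across tumor types: differential expression with a signed
    fold-change on log2 expression, quartile/outlier expression calling
    against matched normal tissue, beta-value methylation state profiling,
    pooled and per-cohort Pearson correlation between expression,
    450K methylation and RPPA protein levels, cross-cohort concordance
    networks, four-group promoter/gene-body methylation stratification, and
    Kaplan-Meier log-rank survival annotation. Includes a synthetic
    multi-cohort generator with planted effects (tumor shifts, promoter and
    gene-body methylation couplings, protein correlations, survival hazards)
    so every stage can be validated against known ground truth, and readers
    and writers for Xena-style tab-separated matrices.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
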
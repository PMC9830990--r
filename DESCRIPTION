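Package: divexpr
Title: Sex-Specific Transcriptome Divergence Under Experimental Evolution
Version: 0.1.0
Authors@R: person("divexpr", "maintainers", email = "divexpr@example.org",
    role = c("aut", "cre"))
Description: A reusable analysis pipeline for replicated experimental-evolution
    RNA-seq designs with two selection regimes, replicate lines, two sexes and
    two tissue pools. Provides negative-binomial GLM differential expression
    with TMM normalization and tagwise Cox-Reid dispersion shrinkage, a
    geometric multivariate repeatability statistic on PCA ordinations with
    bootstrap confidence intervals, sex-biased gene classification and
    sexualization/desexualization comparisons, candidate-gene and gene-set
    enrichment tests, a saturating divergence-curve model with between-sex
    parameter comparison, and a fully specified synthetic count generator with
    ground truth so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    edgeR,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
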
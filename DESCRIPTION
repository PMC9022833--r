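Package: pharmtx
Title: Medication-Transcriptome Association Analysis with Hierarchical
    Replication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for estimating the impact of medication
    (active substances, coded as binary intake indicators) on blood
    gene-expression microarray data. Covers probe detection filtering,
    quantile normalization, Mahalanobis-distance sample quality control,
    empirical-Bayes batch adjustment with ANOVA verification,
    polymedication covariate selection with odds-ratio based collinearity
    pruning, per-substance differential expression with moderated
    t-statistics and Benjamini-Hochberg false discovery rate control,
    hierarchical replication testing across substance families
    (Benjamini-Bogomolov), and hypergeometric gene-set
    over-representation of replicated genes. Includes a synthetic cohort
    generator with planted effects for power, calibration and recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    limma,
    fgsea,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
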
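Package: grextwas
Title: Two-Stage Transcriptome-Wide Association Analysis with Imputed Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage transcriptome-wide association study (TWAS) pipeline for
    small reference panels. Stage one trains per-gene cis-eQTL weight models on a
    reference panel with both genotypes and normalized expression, using elastic-net
    regression and a nonparametric Bayesian Dirichlet-process regression (a
    truncated scale-mixture-of-normals prior fitted by variational inference), with
    or without fivefold cross-validated accuracy estimation. Stage two imputes
    genetically regulated expression (GReX) into a genotyped test panel and runs
    covariate-adjusted per-gene TWAS and per-SNP GWAS linear-model scans with
    identity-by-state MDS stratification components, Bonferroni and
    Benjamini-Hochberg correction, genomic-inflation diagnostics, and comparative
    reporting (Manhattan/QQ tables, top-hit gene annotation, method overlap).
    Includes genotype quality-control profiles, expression normalization and
    covariate residualization, and a synthetic-data generator that emulates the
    genotype-expression-phenotype structure the models assume so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    vcfR
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
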
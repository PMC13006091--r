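Package: gvitgp
Title: Genomic Prediction with a GRM-Fused Vision Transformer over SNP Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end genomic prediction for quantitative traits from
    biallelic SNP dosage data. Quality-controlled marker panels are reduced
    by gradient-boosted-tree locus selection, tokenized by selective patch
    embedding, and modelled by a Pre-LN transformer encoder whose SNP tokens
    cross-attend to a VanRaden genomic-relationship representation, injecting
    kinship structure as an inductive bias. Includes PLINK text and TSV
    genotype readers with call-rate/MAF/Hardy-Weinberg filtering, fold-aware
    (leakage-free) genomic relationship features, alternative locus selectors
    (linear-kernel SVR weights, single-marker GWAS with LD pruning), a nested
    cross-validation training protocol with a GBLUP-style kernel-ridge
    baseline, ablation harnesses, attention-to-genome interpretability
    exports, and a synthetic population simulator (family structure, local
    LD, additive and epistatic architecture, controlled heritability) that
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    xgboost,
    e1071,
    jsonlite,
    ggplot2,
    MASS
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
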
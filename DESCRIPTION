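Package: ForestGWAS
Title: Random-Forest Association Analysis for Complex Phenotypes on
    Ordinal Genotype Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trains random-forest classifiers on ordinal genotype matrices
    (0/1/2 allele counts) to rank genomic variants by Gini importance,
    capturing both marginal (polygenic) and epistatic association signal
    that per-variant tests miss. Tree induction follows a vertical
    (variant-wise) partitioning contract: candidate variants are evaluated
    per column block and only local best splits are aggregated, with
    counter-based random-number streams so trained models are bit-identical
    for any block count or tree-batch size. Includes simulators for random
    genotypes and for polygenic, epistatic (parity/XOR) and mixed complex
    phenotypes with truth bookkeeping; a logistic-regression Wald baseline
    with principal-component covariates; and evaluation metrics (top-r
    truth-variant recovery, maximum-correlation gamma scores, exclusive
    detection counts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    randomForest
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
Collate: 
    'ForestGWAS-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'assoc.R'
    'cli.R'
    'forest.R'
    'genodata.R'
    'simulate.R'
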
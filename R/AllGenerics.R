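#' @include ForestGWAS-package.R
NULL

#' Number of samples
#'
#' @param x a \linkS4class{GenotypeMatrix} or \linkS4class{PhenotypeVector}.
#' @return Integer scalar.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Number of variants
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return Integer scalar.
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' Variant identifiers
#'
#' @param x a \linkS4class{GenotypeMatrix} or \linkS4class{ForestModel}.
#' @return Character vector of variant ids in column order.
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' Sample identifiers
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return Character vector of sample ids in row order.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Genotype values
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return Integer matrix, samples in rows and variants in columns.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' Phenotype class codes
#'
#' @param x a \linkS4class{PhenotypeVector}.
#' @return Integer vector of 0-based class codes, one per sample.
#' @export
setGeneric("classCodes", function(x) standardGeneric("classCodes"))

#' Phenotype class names
#'
#' @param x a \linkS4class{PhenotypeVector} or \linkS4class{ForestModel}.
#' @return Character vector; position \code{k + 1} names class code \code{k}.
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' Truth-variant indices of a truth set
#'
#' @param x a \linkS4class{TruthSet}.
#' @return Sorted integer vector of variant indices that belong to at least
#'   one truth-variable.
#' @export
setGeneric("truthVariants", function(x) standardGeneric("truthVariants"))

#' Per-variant importance scores
#'
#' @param object a trained \linkS4class{ForestModel}.
#' @param weighted logical; if \code{TRUE} (default) each split's Gini gain is
#'   weighted by the fraction of the bootstrap sample reaching the node before
#'   averaging over trees, if \code{FALSE} gains are averaged unweighted.
#' @return Named numeric vector (names are variant ids), zero for variants
#'   never chosen as a best split.
#' @export
setGeneric("importanceScores",
           function(object, weighted = TRUE) standardGeneric("importanceScores"))

#' Out-of-bag misclassification rate
#'
#' With only a model, returns the rate stored at training time.  With the
#' genotype matrix and labels, recomputes it from the retained bootstrap
#' membership: each sample is predicted by majority vote over the trees whose
#' bootstrap excluded it (ties vote for the lowest class code), and the error
#' is the misclassified fraction among samples with at least one such vote.
#'
#' @param object a trained \linkS4class{ForestModel}.
#' @param x optional \linkS4class{GenotypeMatrix} used for recomputation.
#' @param y optional \linkS4class{PhenotypeVector} used for recomputation.
#' @return Numeric scalar in \[0, 1\].
#' @export
setGeneric("oobError", function(object, x, y) standardGeneric("oobError"))

#' Average tree shape of a trained forest
#'
#' @param object a trained \linkS4class{ForestModel}.
#' @return Named numeric vector \code{c(avgDepth, avgNodes)}: the mean over
#'   trees of the maximum leaf depth (root at depth 0) and of the number of
#'   internal (split) nodes per tree.
#' @export
setGeneric("modelStats", function(object) standardGeneric("modelStats"))
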
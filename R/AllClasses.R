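#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## GenotypeMatrix
## ---------------------------------------------------------------------------

#' GenotypeMatrix: ordinal genotypes for nS samples by nV variants
#'
#' Columnar container for ordinal genotype data.  Samples are rows, variants
#' are columns, and every stored value is an allele count in
#' \code{0..ordinalMax} (the VCF encoding maps 0/0, 0/1, 1/1 to 0, 1, 2).
#' A single variant's vector is one matrix column, so per-variant access is
#' O(nS) without copying the matrix.
#'
#' @slot genotypes integer matrix, \code{nS x nV}.
#' @slot variantIds character, unique, one per column (\code{chrom:pos:ref:alt}
#'   for VCF input, the header for CSV input).
#' @slot sampleIds character, unique, one per row.
#' @slot ordinalMax integer, largest admissible genotype value (default 2).
#' @export
setClass("GenotypeMatrix",
         representation(genotypes = "matrix",
                        variantIds = "character",
                        sampleIds = "character",
                        ordinalMax = "integer"))

setValidity("GenotypeMatrix", function(object) {
  g <- object@genotypes
  msg <- character(0)
  if (!is.integer(g))
    msg <- c(msg, "genotypes must be an integer matrix")
  if (length(object@variantIds) != ncol(g))
    msg <- c(msg, "length(variantIds) must equal ncol(genotypes)")
  if (length(object@sampleIds) != nrow(g))
    msg <- c(msg, "length(sampleIds) must equal nrow(genotypes)")
  if (anyDuplicated(object@variantIds))
    msg <- c(msg, "duplicate variant ids")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "duplicate sample ids")
  if (length(object@ordinalMax) != 1L || is.na(object@ordinalMax) ||
      object@ordinalMax < 1L)
    msg <- c(msg, "ordinalMax must be a positive integer")
  if (is.integer(g) && length(g)) {
    if (anyNA(g))
      msg <- c(msg, "genotypes contain NA after missing-value resolution")
    else if (min(g) < 0L || max(g) > object@ordinalMax)
      msg <- c(msg, sprintf("genotypes outside {0..%d}", object@ordinalMax))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param genotypes numeric/integer matrix of ordinal genotypes, samples in
#'   rows, variants in columns.
#' @param variantIds,sampleIds optional identifier vectors; default to the
#'   dimnames or to \code{V1..VnV} / \code{S1..SnS}.
#' @param ordinalMax largest admissible genotype value.
#' @return A \linkS4class{GenotypeMatrix}.
#' @examples
#' gm <- GenotypeMatrix(matrix(c(0L, 1L, 2L, 1L), 2, 2))
#' nSamples(gm); nVariants(gm)
#' @export
GenotypeMatrix <- function(genotypes, variantIds = NULL, sampleIds = NULL,
                           ordinalMax = 2L) {
  if (!is.matrix(genotypes))
    stop("genotypes must be a matrix")
  if (is.null(variantIds))
    variantIds <- colnames(genotypes)
  if (is.null(variantIds))
    variantIds <- paste0("V", seq_len(ncol(genotypes)))
  if (is.null(sampleIds))
    sampleIds <- rownames(genotypes)
  if (is.null(sampleIds))
    sampleIds <- paste0("S", seq_len(nrow(genotypes)))
  storage.mode(genotypes) <- "integer"
  dimnames(genotypes) <- NULL
  new("GenotypeMatrix", genotypes = genotypes,
      variantIds = as.character(variantIds),
      sampleIds = as.character(sampleIds),
      ordinalMax = as.integer(ordinalMax))
}

#' @rdname nSamples
#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@genotypes))

#' @rdname nVariants
#' @export
setMethod("nVariants", "GenotypeMatrix", function(x) ncol(x@genotypes))

#' @rdname variantIds
#' @export
setMethod("variantIds", "GenotypeMatrix", function(x) x@variantIds)

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) x@sampleIds)

#' @rdname genotypes
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) x@genotypes)

#' Extract one variant's genotype vector
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param j variant index (1-based) or variant id.
#' @return Integer vector of length \code{nSamples(x)}.
#' @export
variantColumn <- function(x, j) {
  stopifnot(is(x, "GenotypeMatrix"))
  if (is.character(j)) {
    j <- match(j, x@variantIds)
    if (anyNA(j)) stop("unknown variant id")
  }
  x@genotypes[, j]
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d samples x %d variants (values 0..%d)\n",
              nSamples(object), nVariants(object), object@ordinalMax))
  cat("  variants: ", paste(head(object@variantIds, 4L), collapse = ", "),
      if (nVariants(object) > 4L) ", ..." else "", "\n", sep = "")
  cat("  samples:  ", paste(head(object@sampleIds, 4L), collapse = ", "),
      if (nSamples(object) > 4L) ", ..." else "", "\n", sep = "")
})

## ---------------------------------------------------------------------------
## PhenotypeVector
## ---------------------------------------------------------------------------

#' PhenotypeVector: per-sample class labels
#'
#' Class labels stored as 0-based codes together with their names (position
#' \code{k + 1} of \code{classNames} is the name of code \code{k}).  Binary
#' case/control is the default GWAS situation, but any number of classes is
#' supported.
#'
#' @slot codes integer vector in \code{0..K-1}.
#' @slot classNames ordered character vector of the K class names.
#' @export
setClass("PhenotypeVector",
         representation(codes = "integer", classNames = "character"))

setValidity("PhenotypeVector", function(object) {
  k <- length(object@classNames)
  msg <- character(0)
  if (k < 1L) msg <- c(msg, "at least one class name required")
  if (anyDuplicated(object@classNames)) msg <- c(msg, "duplicate class names")
  if (length(object@codes) &&
      (anyNA(object@codes) || min(object@codes) < 0L ||
       max(object@codes) >= k))
    msg <- c(msg, "codes must lie in 0..K-1")
  if (length(msg)) msg else TRUE
})

#' Construct a PhenotypeVector
#'
#' Accepts a factor, a character vector, or an integer vector of 0-based
#' codes.  For factor/character input the class names are the sorted unique
#' labels mapped to codes \code{0..K-1}.
#'
#' @param labels factor, character, or integer labels, one per sample.
#' @param classNames explicit class names when \code{labels} is integer.
#' @return A \linkS4class{PhenotypeVector}.
#' @examples
#' y <- PhenotypeVector(c("ctrl", "case", "case"))
#' classCodes(y)   # 1 0 0 ("case" sorts first)
#' @export
PhenotypeVector <- function(labels, classNames = NULL) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    classNames <- sort(unique(labels))
    codes <- match(labels, classNames) - 1L
  } else {
    codes <- as.integer(labels)
    if (is.null(classNames))
      classNames <- as.character(sort(unique(codes)))
  }
  new("PhenotypeVector", codes = codes, classNames = as.character(classNames))
}

#' @rdname nSamples
#' @export
setMethod("nSamples", "PhenotypeVector", function(x) length(x@codes))

#' @rdname classCodes
#' @export
setMethod("classCodes", "PhenotypeVector", function(x) x@codes)

#' @rdname classNames
#' @export
setMethod("classNames", "PhenotypeVector", function(x) x@classNames)

setMethod("show", "PhenotypeVector", function(object) {
  tab <- tabulate(object@codes + 1L, length(object@classNames))
  cat(sprintf("PhenotypeVector: %d samples, %d classes (%s)\n",
              length(object@codes), length(object@classNames),
              paste(sprintf("%s=%d", object@classNames, tab),
                    collapse = ", ")))
})

## ---------------------------------------------------------------------------
## ColumnBlock
## ---------------------------------------------------------------------------

#' ColumnBlock: a contiguous span of variant columns
#'
#' Vertical (variant-wise) partitioning assigns each worker a contiguous,
#' closed 1-based span \code{[start, end]} of variant indices.  Membership is
#' computable from the span alone, no lookup table is needed, and
#' reassembling the blocks in order reproduces the matrix exactly.
#'
#' @slot blockIndex 1-based index of the block.
#' @slot start,end first and last owned variant index (closed range).
#' @export
setClass("ColumnBlock",
         representation(blockIndex = "integer", start = "integer",
                        end = "integer"))

setValidity("ColumnBlock", function(object) {
  if (object@start < 1L || object@end < object@start)
    "need 1 <= start <= end" else TRUE
})

#' Variant span of a column block
#'
#' @param block a \linkS4class{ColumnBlock}.
#' @return Integer vector of the owned variant indices.
#' @export
variantSpan <- function(block) seq.int(block@start, block@end)

setMethod("show", "ColumnBlock", function(object) {
  cat(sprintf("ColumnBlock %d: variants [%d, %d] (%d columns)\n",
              object@blockIndex, object@start, object@end,
              object@end - object@start + 1L))
})

## ---------------------------------------------------------------------------
## ForestParams
## ---------------------------------------------------------------------------

#' ForestParams: random-forest hyper-parameters
#'
#' @slot nTree number of trees in the forest.
#' @slot mTry number of candidate variants evaluated at each node.  May be
#'   given as \code{NA} (resolved to \code{round(sqrt(nV))}, the usual rule of
#'   thumb), as a fraction in (0,1) of nV, or as an absolute count.
#' @slot maxD maximum tree depth, root at depth 0; \code{Inf} for unlimited.
#' @slot minNS minimum number of samples a node must hold to be processed;
#'   smaller nodes become leaves without evaluation.
#' @slot rbs number of trees grown per batch; \code{NA} resolves to
#'   \code{min(100, nTree)}.  Purely a scheduling knob: the trained model is
#'   identical for every value.
#' @slot seed master seed from which all per-tree and per-node streams are
#'   derived.
#' @export
setClass("ForestParams",
         representation(nTree = "integer", mTry = "numeric", maxD = "numeric",
                        minNS = "numeric", rbs = "integer", seed = "integer"))

setValidity("ForestParams", function(object) {
  msg <- character(0)
  if (object@nTree < 1L) msg <- c(msg, "nTree must be >= 1")
  if (!is.na(object@mTry) && object@mTry <= 0)
    msg <- c(msg, "mTry must be positive (or NA for sqrt rule)")
  if (object@maxD < 1) msg <- c(msg, "maxD must be >= 1 (or Inf)")
  if (object@minNS < 2) msg <- c(msg, "minNS must be >= 2")
  if (!is.na(object@rbs) && (object@rbs < 1L || object@rbs > object@nTree))
    msg <- c(msg, "rbs must satisfy 1 <= rbs <= nTree")
  if (length(msg)) msg else TRUE
})

#' Construct ForestParams
#'
#' @param nTree trees in the forest.
#' @param mTry candidates per node: \code{NA} for \code{round(sqrt(nV))}, a
#'   fraction in (0,1) of nV, or an absolute count.
#' @param maxD maximum depth (root depth 0), \code{Inf} for unlimited.
#' @param minNS minimum node size to be processed (>= 2).
#' @param rbs trees per batch (\code{NA}: \code{min(100, nTree)}).
#' @param seed master RNG seed.
#' @return A \linkS4class{ForestParams}.
#' @examples
#' ForestParams(nTree = 1000, mTry = 0.1, maxD = 15, minNS = 50)
#' @export
ForestParams <- function(nTree = 100L, mTry = NA_real_, maxD = Inf,
                         minNS = 2, rbs = NA_integer_, seed = 1L) {
  new("ForestParams", nTree = as.integer(nTree), mTry = as.numeric(mTry),
      maxD = as.numeric(maxD), minNS = as.numeric(minNS),
      rbs = as.integer(rbs), seed = as.integer(seed))
}

setMethod("show", "ForestParams", function(object) {
  cat(sprintf(
    "ForestParams: nTree=%d, mTry=%s, maxD=%s, minNS=%s, rbs=%s, seed=%d\n",
    object@nTree,
    if (is.na(object@mTry)) "sqrt(nV)" else format(object@mTry),
    format(object@maxD), format(object@minNS),
    if (is.na(object@rbs)) "auto" else format(object@rbs), object@seed))
})

## ---------------------------------------------------------------------------
## SplitCandidate
## ---------------------------------------------------------------------------

#' SplitCandidate: one evaluated binary split of an ordinal variant
#'
#' Splitting sends samples with genotype \code{<= threshold} left and the
#' rest right.  \code{gain} is the Gini information gained,
#' \code{imp(parent) - (nL/n) imp(L) - (nR/n) imp(R)}.
#'
#' @slot variantIndex global 1-based variant index.
#' @slot threshold ordinal cut (0 or 1 for 0/1/2 genotypes).
#' @slot gain Gini information gained (> 0 for an accepted split).
#' @slot leftSize,rightSize child sample counts (both >= 1).
#' @export
setClass("SplitCandidate",
         representation(variantIndex = "integer", threshold = "integer",
                        gain = "numeric", leftSize = "integer",
                        rightSize = "integer"))

setValidity("SplitCandidate", function(object) {
  msg <- character(0)
  if (object@gain < 0) msg <- c(msg, "gain must be >= 0")
  if (object@leftSize < 1L || object@rightSize < 1L)
    msg <- c(msg, "both children must be non-empty")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SplitCandidate", function(object) {
  cat(sprintf(
    "SplitCandidate: variant %d, g <= %d, gain %.6g, sizes %d|%d\n",
    object@variantIndex, object@threshold, object@gain, object@leftSize,
    object@rightSize))
})

## ---------------------------------------------------------------------------
## TruthSet
## ---------------------------------------------------------------------------

#' TruthSet: simulated drivers of a phenotype
#'
#' Bookkeeping for simulated phenotypes.  Each truth-variable is either a
#' single variant (1-way) or a set of n interacting variants (n-way); the
#' truth-variants are the union of all members, the targets of recovery
#' evaluation.  Variables are pairwise disjoint: a variant belongs to at most
#' one variable.
#'
#' @slot variables list of \code{list(order, members, weight)}; \code{members}
#'   are 1-based variant indices.
#' @slot truthVariants sorted union of all member indices.
#' @slot metadata list of generator settings (noise-variant indices, gm, gs,
#'   carrier probability, ...).
#' @export
setClass("TruthSet",
         representation(variables = "list", truthVariants = "integer",
                        metadata = "list"))

setValidity("TruthSet", function(object) {
  members <- unlist(lapply(object@variables, `[[`, "members"))
  msg <- character(0)
  if (anyDuplicated(members))
    msg <- c(msg, "truth-variables must be pairwise disjoint")
  if (!identical(sort(unique(as.integer(members))), object@truthVariants) &&
      length(members))
    msg <- c(msg, "truthVariants must be the sorted union of members")
  for (v in object@variables)
    if (v$order != length(v$members))
      msg <- c(msg, "variable order must equal its member count")
  if (length(msg)) msg else TRUE
})

#' @rdname truthVariants
#' @export
setMethod("truthVariants", "TruthSet", function(x) x@truthVariants)

setMethod("show", "TruthSet", function(object) {
  orders <- vapply(object@variables, `[[`, numeric(1), "order")
  cat(sprintf("TruthSet: %d truth-variables, %d truth-variants\n",
              length(object@variables), length(object@truthVariants)))
  if (length(orders))
    cat("  by order: ",
        paste(sprintf("%d-way=%d", sort(unique(orders)),
                      as.integer(table(orders))), collapse = ", "),
        "\n", sep = "")
})

## ---------------------------------------------------------------------------
## ForestModel
## ---------------------------------------------------------------------------

#' ForestModel: a trained random forest
#'
#' Trees are stored as flat node tables (one row per node, children referenced
#' by row) together with the bootstrap membership of every tree, so both the
#' out-of-bag error and the importance scores can be recomputed from the
#' model.
#'
#' @slot trees list of per-tree node data frames with columns \code{nodeId},
#'   \code{depth}, \code{size}, \code{variant}, \code{threshold}, \code{gain},
#'   \code{left}, \code{right}, \code{leafClass}.
#' @slot inBag list of integer vectors: the bootstrap sample (with
#'   repetition) of each tree.
#' @slot importance node-size-weighted mean Gini gain per variant.
#' @slot importanceUnweighted unweighted variant (mean gain over trees).
#' @slot oobError out-of-bag misclassification rate at training time.
#' @slot params resolved \linkS4class{ForestParams} used for training.
#' @slot variantIds,classNames copied from the training data.
#' @slot nSamples training sample count.
#' @slot treeDepths,treeNodeCounts per-tree maximum leaf depth and internal
#'   node count.
#' @export
setClass("ForestModel",
         representation(trees = "list", inBag = "list",
                        importance = "numeric",
                        importanceUnweighted = "numeric",
                        oobError = "numeric", params = "ForestParams",
                        variantIds = "character", classNames = "character",
                        nSamples = "integer", treeDepths = "numeric",
                        treeNodeCounts = "numeric"))

setValidity("ForestModel", function(object) {
  msg <- character(0)
  if (length(object@trees) != object@params@nTree)
    msg <- c(msg, "tree count must equal nTree")
  if (length(object@oobError) == 1L && !is.na(object@oobError) &&
      (object@oobError < 0 || object@oobError > 1))
    msg <- c(msg, "oobError must lie in [0, 1]")
  if (any(object@importance < 0))
    msg <- c(msg, "importance scores must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname variantIds
#' @export
setMethod("variantIds", "ForestModel", function(x) x@variantIds)

#' @rdname classNames
#' @export
setMethod("classNames", "ForestModel", function(x) x@classNames)

setMethod("show", "ForestModel", function(object) {
  cat(sprintf("ForestModel: %d trees over %d variants, %d samples\n",
              length(object@trees), length(object@variantIds),
              object@nSamples))
  cat(sprintf("  OOB error: %.4f | avg depth: %.2f | avg split nodes: %.2f\n",
              object@oobError, mean(object@treeDepths),
              mean(object@treeNodeCounts)))
  top <- order(-object@importance)[seq_len(min(3L, length(object@importance)))]
  cat("  top importance: ",
      paste(sprintf("%s=%.4g", object@variantIds[top],
                    object@importance[top]), collapse = ", "), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## RankedVariants
## ---------------------------------------------------------------------------

#' RankedVariants: variants ordered by an association score
#'
#' A total order over variants by score descending, ties broken by variant
#' index ascending, missing scores last.  Scores are importance values for
#' the forest or \code{-log10(p)} for the regression baseline.
#'
#' @slot index original 1-based variant indices in rank order.
#' @slot ids variant ids in rank order.
#' @slot scores scores in rank order (\code{NA} for missing).
#' @slot decreasing logical: \code{TRUE} when higher scores rank first
#'   (importance), \code{FALSE} when lower scores rank first (p-values).
#' @slot method label of the ranking method.
#' @export
setClass("RankedVariants",
         representation(index = "integer", ids = "character",
                        scores = "numeric", decreasing = "logical",
                        method = "character"))

setValidity("RankedVariants", function(object) {
  msg <- character(0)
  if (length(object@index) != length(object@ids) ||
      length(object@index) != length(object@scores))
    msg <- c(msg, "index, ids and scores must have equal length")
  if (anyDuplicated(object@index)) msg <- c(msg, "duplicate variants in ranking")
  s <- object@scores
  ok <- !is.na(s)
  if (any(!ok) && any(ok) && max(which(ok)) > min(which(!ok)))
    msg <- c(msg, "missing scores must be ranked last")
  if (any(ok) && is.unsorted(if (object@decreasing) -s[ok] else s[ok]))
    msg <- c(msg, "scores must be monotone in rank order")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RankedVariants", function(object) {
  cat(sprintf("RankedVariants (%s): %d variants\n", object@method,
              length(object@index)))
  n <- min(5L, length(object@index))
  if (n)
    cat("  top: ", paste(sprintf("%s (%.4g)", object@ids[seq_len(n)],
                                 object@scores[seq_len(n)]),
                         collapse = ", "), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## EvalReport
## ---------------------------------------------------------------------------

#' EvalReport: truth-variant recovery evaluation of ranked variants
#'
#' @slot recovery matrix of recovery fractions, one row per method and one
#'   column per rank cutoff multiplier (r = m * t).
#' @slot gamma matrix of per-truth-variant gamma scores (maximum absolute
#'   Pearson correlation with any top-10t ranked variant), one column per
#'   method.
#' @slot exclusive named integer vector of exclusive-detection counts for the
#'   method pair.
#' @slot nTruth number of truth-variants (t).
#' @export
setClass("EvalReport",
         representation(recovery = "matrix", gamma = "matrix",
                        exclusive = "integer", nTruth = "integer"))

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d truth-variants\n", object@nTruth))
  cat("  recovery:\n")
  print(round(object@recovery, 3))
  if (length(object@exclusive)) {
    cat("  exclusive detections: ",
        paste(sprintf("%s=%d", names(object@exclusive), object@exclusive),
              collapse = ", "), "\n", sep = "")
  }
})
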
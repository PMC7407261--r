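#' @include AllClasses.R
NULL

## Gains that are mathematically zero can round to +-1e-17 in floating point;
## a split must clear this tolerance to be accepted.
.GAIN_TOL <- 1e-12

## Counter-based derivation of RNG streams.  Every per-tree stream is
## mixSeed(seed, treeIndex) and every per-node stream is
## mixSeed(treeSeed, nodeId) (the bootstrap uses counter 0, node ids start at
## 1), so a tree's randomness depends only on (seed, treeIndex, nodeId) —
## never on the batch schedule or the column partitioning.  Plain modular
## arithmetic below 2^31 keeps every intermediate exact in doubles.
.mixSeed <- function(a, b) {
  m <- 2147483647
  h <- as.numeric(a) %% m
  h <- (h * 69069 + (as.numeric(b) %% m) + 1) %% m
  h <- (h * 69069 + 12345) %% m
  as.integer(h)
}

#' Gini impurity of a node
#'
#' \code{1 - sum(p_c^2)} with \code{p_c} the class proportions.  0 for a pure
#' node; \code{(K-1)/K} for K equally frequent classes.
#'
#' @param classCounts non-negative integer vector of per-class sample counts
#'   (at least one sample in total).
#' @return Numeric scalar in \[0, 1).
#' @examples
#' giniImpurity(c(5, 5))        # 0.5
#' giniImpurity(c(1, 1, 1, 1))  # 0.75
#' @export
giniImpurity <- function(classCounts) {
  if (any(classCounts < 0)) stop("negative class count")
  n <- sum(classCounts)
  if (n < 1) stop("empty node")
  1 - sum((classCounts / n)^2)
}

## Raw best split over a candidate set: numeric c(variant, threshold, gain,
## nL, nR) or NULL.  Shared by the exported bestSplit() and the tree grower
## so both paths pick identical splits.
.evalBest <- function(G, idx, y, K, cand, gmax) {
  r <- .evalBlockBestC(G, idx, y, K, as.integer(cand), gmax, .GAIN_TOL)
  if (length(r)) r else NULL
}

## Lexicographic comparison used everywhere a winner is chosen:
## gain desc, variant asc, threshold asc.  Returns TRUE when a beats b.
.beats <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (a[3L] != b[3L]) return(a[3L] > b[3L])
  if (a[1L] != b[1L]) return(a[1L] < b[1L])
  a[2L] < b[2L]
}

#' Best local split within a column block
#'
#' Exhaustively evaluates the binary threshold splits (\code{g <= 0},
#' \code{g <= 1} for 0/1/2 genotypes) of every candidate variant owned by the
#' block and returns the one maximizing the Gini gain
#' \code{imp(parent) - (nL/n) imp(L) - (nR/n) imp(R)}, or \code{NULL} when no
#' split has positive gain with both children non-empty.  Ties break by
#' lower variant index, then lower threshold, which makes the winner
#' independent of how variants are spread over blocks.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param block the \linkS4class{ColumnBlock} doing the evaluation.
#' @param nodeSampleIndex 1-based sample indices of the node (a bootstrap
#'   multiset: repeats count).
#' @param y a \linkS4class{PhenotypeVector}.
#' @param candidates global variant indices to evaluate; all must be owned by
#'   \code{block}.
#' @return A \linkS4class{SplitCandidate} or \code{NULL}.
#' @export
bestSplit <- function(x, block, nodeSampleIndex, y, candidates) {
  stopifnot(is(x, "GenotypeMatrix"), is(block, "ColumnBlock"),
            is(y, "PhenotypeVector"))
  if (any(candidates < block@start | candidates > block@end))
    stop("candidate variant outside the block's span")
  r <- .evalBest(genotypes(x), as.integer(nodeSampleIndex), classCodes(y),
                 length(classNames(y)), candidates, x@ordinalMax)
  if (is.null(r)) return(NULL)
  new("SplitCandidate", variantIndex = as.integer(r[1L]),
      threshold = as.integer(r[2L]), gain = r[3L],
      leftSize = as.integer(r[4L]), rightSize = as.integer(r[5L]))
}

#' Aggregate local best splits into the global best
#'
#' The master-side half of the vertical-partitioning contract: each block
#' reports only its best local split and the global winner is the argmax by
#' (gain descending, variant index ascending, threshold ascending).
#'
#' @param locals list with one entry per block: a
#'   \linkS4class{SplitCandidate} or \code{NULL}.
#' @return A \linkS4class{SplitCandidate}, or \code{NULL} if all entries are
#'   \code{NULL} (the node becomes a leaf).
#' @export
aggregateLocalBests <- function(locals) {
  best <- NULL
  for (sc in locals) {
    if (is.null(sc)) next
    a <- c(sc@variantIndex, sc@threshold, sc@gain)
    if (is.null(best) || .beats(a, b = c(best@variantIndex, best@threshold,
                                         best@gain)))
      best <- sc
  }
  best
}

## Core tree grower.  Returns list(nodes = <list of parallel vectors>,
## bag = bootstrap indices).  Nodes are created in breadth-first order and
## the creation rank is the node id used to derive the node's RNG stream.
.growTreeRaw <- function(G, y, K, mTry, maxD, minNS, blockSpans, treeSeed,
                         bootstrap, gmax) {
  nS <- nrow(G); nV <- ncol(G)
  if (bootstrap) {
    set.seed(.mixSeed(treeSeed, 0L))
    ## sorted for memory locality; nodes are sample multisets, so order is
    ## semantically irrelevant
    bag <- sort.int(sample.int(nS, nS, replace = TRUE), method = "radix")
  } else {
    bag <- seq_len(nS)
  }
  cap <- 64L
  depth <- integer(cap); size <- integer(cap); variant <- integer(cap)
  threshold <- integer(cap); gain <- numeric(cap); left <- integer(cap)
  right <- integer(cap); leafClass <- integer(cap)
  pendIdx <- vector("list", cap)
  nNodes <- 1L
  depth[1L] <- 0L; pendIdx[[1L]] <- bag
  ensure <- function(n) {
    if (n > cap) {
      newCap <- max(n, cap * 2L)
      length(depth) <<- newCap; length(size) <<- newCap
      length(variant) <<- newCap; length(threshold) <<- newCap
      length(gain) <<- newCap; length(left) <<- newCap
      length(right) <<- newCap; length(leafClass) <<- newCap
      length(pendIdx) <<- newCap
      cap <<- newCap
    }
  }
  node <- 1L
  while (node <= nNodes) {
    idx <- pendIdx[[node]]
    pendIdx[node] <- list(NULL)
    n <- length(idx)
    size[node] <- n
    counts <- .classCountsC(idx, y, K)
    majority <- which.max(counts) - 1L   # tie -> lowest class code
    pure <- sum(counts > 0L) <= 1L
    best <- NULL
    if (!pure && n >= minNS && depth[node] < maxD && n >= 2L) {
      set.seed(.mixSeed(treeSeed, node))
      cand <- sample.int(nV, mTry)
      for (b in blockSpans) {
        bc <- cand[cand >= b[1L] & cand <= b[2L]]
        if (!length(bc)) next
        r <- .evalBest(G, idx, y, K, bc, gmax)
        if (!is.null(r) && (is.null(best) || .beats(r, best)))
          best <- r
      }
    }
    if (is.null(best)) {
      variant[node] <- NA_integer_; threshold[node] <- NA_integer_
      gain[node] <- NA_real_; left[node] <- NA_integer_
      right[node] <- NA_integer_; leafClass[node] <- majority
    } else {
      v <- as.integer(best[1L]); thr <- as.integer(best[2L])
      sel <- G[idx, v] <= thr
      ensure(nNodes + 2L)
      lid <- nNodes + 1L; rid <- nNodes + 2L
      nNodes <- nNodes + 2L
      depth[lid] <- depth[node] + 1L; depth[rid] <- depth[node] + 1L
      pendIdx[[lid]] <- idx[sel]; pendIdx[[rid]] <- idx[!sel]
      variant[node] <- v; threshold[node] <- thr; gain[node] <- best[3L]
      left[node] <- lid; right[node] <- rid; leafClass[node] <- NA_integer_
    }
    node <- node + 1L
  }
  keep <- seq_len(nNodes)
  list(nodes = data.frame(nodeId = keep, depth = depth[keep],
                          size = size[keep], variant = variant[keep],
                          threshold = threshold[keep], gain = gain[keep],
                          left = left[keep], right = right[keep],
                          leafClass = leafClass[keep]),
       bag = bag)
}

## Resolve mTry: NA -> round(sqrt(nV)); fraction in (0,1) -> round(f * nV);
## otherwise an absolute count, clamped to [1, nV].
.resolveMTry <- function(mTry, nV) {
  m <- if (is.na(mTry)) round(sqrt(nV))
       else if (mTry > 0 && mTry < 1) round(mTry * nV)
       else round(mTry)
  as.integer(min(max(m, 1L), nV))
}

.resolveParams <- function(params, nV) {
  ForestParams(nTree = params@nTree,
               mTry = .resolveMTry(params@mTry, nV),
               maxD = params@maxD, minNS = params@minNS,
               rbs = if (is.na(params@rbs)) min(100L, params@nTree)
                     else params@rbs,
               seed = params@seed)
}

#' Grow a single tree of the forest
#'
#' Bootstraps \code{nS} samples with replacement from the tree's own RNG
#' stream, then grows a binary tree breadth-first: at each node \code{mTry}
#' candidate variants are drawn globally without replacement from the node's
#' RNG stream, routed to the owning column blocks, evaluated locally
#' (\code{\link{bestSplit}}) and aggregated
#' (\code{\link{aggregateLocalBests}}).  A node becomes a leaf when it is
#' pure, smaller than \code{minNS}, at depth \code{maxD}, or no split has
#' positive gain; the leaf class is the majority (ties to the lowest class
#' code).
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param y a \linkS4class{PhenotypeVector} with at least two classes present.
#' @param params a \linkS4class{ForestParams}; \code{mTry} is resolved
#'   against \code{nVariants(x)}.
#' @param treeIndex index of the tree in the forest (selects the RNG stream).
#' @param nBlocks number of column blocks to route candidates through; the
#'   result is identical for every value.
#' @param bootstrap set \code{FALSE} to train on the raw sample (test hook;
#'   with \code{mTry = nV} the result is a deterministic decision tree).
#' @return \code{list(nodes, bag)}: the flat node table and the bootstrap
#'   sample.
#' @export
growTree <- function(x, y, params, treeIndex = 1L, nBlocks = 1L,
                     bootstrap = TRUE) {
  stopifnot(is(x, "GenotypeMatrix"), is(y, "PhenotypeVector"),
            is(params, "ForestParams"))
  if (nSamples(x) != nSamples(y))
    stop("genotype matrix and phenotype have different sample counts")
  if (length(unique(classCodes(y))) < 2L)
    stop("training labels contain a single class")
  rp <- .resolveParams(params, nVariants(x))
  spans <- lapply(partitionVariants(x, nBlocks), function(b)
    c(b@start, b@end))
  .growTreeRaw(genotypes(x), classCodes(y), length(classNames(y)),
               rp@mTry, rp@maxD, rp@minNS, spans,
               .mixSeed(rp@seed, treeIndex), bootstrap, x@ordinalMax)
}

## Predict class codes for rows `idx` of G with one tree (flat node table as
## a list of vectors).
.predictTree <- function(tr, G, idx) {
  pred <- integer(length(idx))
  leafClass <- tr$leafClass; variant <- tr$variant
  threshold <- tr$threshold; lft <- tr$left; rgt <- tr$right
  rec <- function(node, sel) {
    if (!is.na(leafClass[node])) {
      pred[sel] <<- leafClass[node]
      return(invisible())
    }
    l <- G[idx[sel], variant[node]] <= threshold[node]
    if (any(l)) rec(lft[node], sel[l])
    if (any(!l)) rec(rgt[node], sel[!l])
  }
  if (length(idx)) rec(1L, seq_along(idx))
  pred
}

#' Train a random forest on a column-partitioned genotype matrix
#'
#' Grows \code{nTree} trees in batches of \code{rbs}.  Per-tree RNG streams
#' are derived only from \code{(seed, treeIndex)} and per-node streams from
#' \code{(tree stream, nodeId)}, so the trained model is bit-identical for
#' any \code{nBlocks} and any \code{rbs} — the partitioning and batching are
#' pure scheduling.  Importance scores and the out-of-bag error are computed
#' as part of training.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param y a \linkS4class{PhenotypeVector} aligned to \code{x}, with at
#'   least two classes present.
#' @param params a \linkS4class{ForestParams}.
#' @param nBlocks number of vertical column blocks.
#' @param bootstrap test hook; \code{FALSE} trains every tree on the raw
#'   sample (OOB is then undefined and reported as \code{NA}).
#' @return A \linkS4class{ForestModel}.
#' @examples
#' gm <- genFeatures(200, 40, seed = 11)
#' sim <- genLabel(gm, LabelSimSpec(kCausal = 2, gm = 0, gs = 0, seed = 11))
#' fit <- trainForest(gm, sim$phenotype,
#'                    ForestParams(nTree = 25, seed = 11))
#' head(sort(importanceScores(fit), decreasing = TRUE))
#' @export
trainForest <- function(x, y, params = ForestParams(), nBlocks = 1L,
                        bootstrap = TRUE) {
  stopifnot(is(x, "GenotypeMatrix"), is(y, "PhenotypeVector"),
            is(params, "ForestParams"))
  if (nSamples(x) != nSamples(y))
    stop("genotype matrix and phenotype have different sample counts")
  if (length(unique(classCodes(y))) < 2L)
    stop("training labels contain a single class")
  nS <- nSamples(x); nV <- nVariants(x)
  K <- length(classNames(y))
  rp <- .resolveParams(params, nV)
  spans <- lapply(partitionVariants(x, nBlocks), function(b)
    c(b@start, b@end))
  G <- genotypes(x); codes <- classCodes(y)

  trees <- vector("list", rp@nTree)
  inBag <- vector("list", rp@nTree)
  imp <- numeric(nV); impU <- numeric(nV)
  votes <- matrix(0L, nS, K)
  treeDepths <- numeric(rp@nTree)
  treeNodeCounts <- numeric(rp@nTree)

  batches <- split(seq_len(rp@nTree),
                   ceiling(seq_len(rp@nTree) / rp@rbs))
  for (batch in batches) {
    grown <- lapply(batch, function(t)
      .growTreeRaw(G, codes, K, rp@mTry, rp@maxD, rp@minNS, spans,
                   .mixSeed(rp@seed, t), bootstrap, x@ordinalMax))
    for (j in seq_along(batch)) {
      t <- batch[j]
      tr <- grown[[j]]$nodes
      trees[[t]] <- tr
      inBag[[t]] <- grown[[j]]$bag
      splitRows <- which(!is.na(tr$variant))
      if (length(splitRows)) {
        v <- tr$variant[splitRows]
        w <- tr$size[splitRows] / nS * tr$gain[splitRows]
        acc <- rowsum(w, v)
        imp[as.integer(rownames(acc))] <-
          imp[as.integer(rownames(acc))] + acc[, 1L]
        accU <- rowsum(tr$gain[splitRows], v)
        impU[as.integer(rownames(accU))] <-
          impU[as.integer(rownames(accU))] + accU[, 1L]
      }
      treeDepths[t] <- max(tr$depth[!is.na(tr$leafClass)])
      treeNodeCounts[t] <- length(splitRows)
      if (bootstrap) {
        oobIdx <- which(tabulate(inBag[[t]], nS) == 0L)
        if (length(oobIdx)) {
          pred <- .predictTree(tr, G, oobIdx)
          votes[cbind(oobIdx, pred + 1L)] <-
            votes[cbind(oobIdx, pred + 1L)] + 1L
        }
      }
    }
  }
  imp <- imp / rp@nTree
  impU <- impU / rp@nTree
  names(imp) <- names(impU) <- variantIds(x)

  oob <- NA_real_
  if (bootstrap) {
    hasVote <- rowSums(votes) > 0L
    if (!any(hasVote))
      stop("no sample has an out-of-bag vote; grow more trees")
    predClass <- max.col(votes, ties.method = "first") - 1L
    oob <- mean(predClass[hasVote] != codes[hasVote])
  }
  new("ForestModel", trees = trees, inBag = inBag, importance = imp,
      importanceUnweighted = impU, oobError = oob, params = rp,
      variantIds = variantIds(x), classNames = classNames(y),
      nSamples = as.integer(nS), treeDepths = treeDepths,
      treeNodeCounts = treeNodeCounts)
}

#' @rdname importanceScores
#' @export
setMethod("importanceScores", "ForestModel", function(object,
                                                      weighted = TRUE) {
  if (weighted) object@importance else object@importanceUnweighted
})

#' @rdname oobError
#' @export
setMethod("oobError", signature("ForestModel", "missing", "missing"),
          function(object, x, y) object@oobError)

#' @rdname oobError
#' @export
setMethod("oobError",
          signature("ForestModel", "GenotypeMatrix", "PhenotypeVector"),
          function(object, x, y) {
  nS <- nSamples(x)
  if (nS != object@nSamples)
    stop("sample count differs from the training data")
  K <- length(object@classNames)
  G <- genotypes(x); codes <- classCodes(y)
  votes <- matrix(0L, nS, K)
  for (t in seq_along(object@trees)) {
    oobIdx <- which(tabulate(object@inBag[[t]], nS) == 0L)
    if (!length(oobIdx)) next
    pred <- .predictTree(object@trees[[t]], G, oobIdx)
    votes[cbind(oobIdx, pred + 1L)] <- votes[cbind(oobIdx, pred + 1L)] + 1L
  }
  hasVote <- rowSums(votes) > 0L
  if (!any(hasVote))
    stop("no sample has an out-of-bag vote; grow more trees")
  predClass <- max.col(votes, ties.method = "first") - 1L
  mean(predClass[hasVote] != codes[hasVote])
})

#' @rdname modelStats
#' @export
setMethod("modelStats", "ForestModel", function(object) {
  c(avgDepth = mean(object@treeDepths),
    avgNodes = mean(object@treeNodeCounts))
})

#' Operation count of forest training
#'
#' The core computation is linear in \code{nTree * nNode * mTry * nS}: every
#' candidate variant at every internal node of every tree is evaluated by a
#' pass over the node's samples.
#'
#' @param nTree trees in the forest.
#' @param nNode average number of internal (split) nodes per tree.
#' @param mTry candidate variants per node.
#' @param nS samples.
#' @return The product, as a double (it overflows integers at genomic scale:
#'   \code{opCount(1e4, 100, 1e7, 1e4)} is 1e17).
#' @export
opCount <- function(nTree, nNode, mTry, nS) {
  stopifnot(nTree > 0, nNode > 0, mTry > 0, nS > 0)
  as.numeric(nTree) * as.numeric(nNode) * as.numeric(mTry) * as.numeric(nS)
}

#' Expected runtime from load time and per-tree train time
#'
#' @param beta data load time (seconds).
#' @param theta average train time per tree (seconds/tree).
#' @param nTree number of trees.
#' @return \code{beta + nTree * theta}, seconds.
#' @export
expectedRuntime <- function(beta, theta, nTree) {
  stopifnot(beta >= 0, theta >= 0, nTree >= 0)
  beta + nTree * theta
}

## nested-list view of one tree, for JSON export
.nestNode <- function(tr, node) {
  if (!is.na(tr$leafClass[node]))
    return(list(size = tr$size[node], leafClass = tr$leafClass[node]))
  list(size = tr$size[node], variant = tr$variant[node],
       threshold = tr$threshold[node], gain = tr$gain[node],
       left = .nestNode(tr, tr$left[node]),
       right = .nestNode(tr, tr$right[node]))
}

#' Export a trained model as JSON
#'
#' Writes the forest as nested per-tree node objects (variant, threshold,
#' gain, size, leaf class) together with per-tree depth and node counts, the
#' resolved parameters, the OOB error and the importance table — enough to
#' recompute tree-shape statistics from the file alone.
#'
#' @param model a \linkS4class{ForestModel}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
exportModelJSON <- function(model, path) {
  stopifnot(is(model, "ForestModel"))
  p <- model@params
  obj <- list(
    params = list(nTree = p@nTree, mTry = p@mTry, maxD = p@maxD,
                  minNS = p@minNS, rbs = p@rbs, seed = p@seed),
    nSamples = model@nSamples,
    classNames = model@classNames,
    oobError = model@oobError,
    treeDepths = model@treeDepths,
    treeNodeCounts = model@treeNodeCounts,
    importance = as.list(model@importance),
    trees = lapply(model@trees, .nestNode, node = 1L))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write ranked importance scores as CSV
#'
#' Columns \code{variant_id, importance, rank} with rank 1 for the highest
#' score (score ties break by variant index).
#'
#' @param model a \linkS4class{ForestModel}.
#' @param path output path.
#' @param weighted passed to \code{\link{importanceScores}}.
#' @return Invisibly, the written data frame.
#' @export
writeImportanceCSV <- function(model, path, weighted = TRUE) {
  stopifnot(is(model, "ForestModel"))
  imp <- importanceScores(model, weighted = weighted)
  ord <- order(-imp, seq_along(imp))
  df <- data.frame(variant_id = names(imp)[ord],
                   importance = unname(imp[ord]),
                   rank = seq_along(imp))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
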
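test_that("Gini impurity matches its closed forms", {
  expect_identical(giniImpurity(c(10, 0)), 0)
  expect_identical(giniImpurity(c(5, 5)), 0.5)
  expect_identical(giniImpurity(c(1, 1, 1, 1)), 0.75)
  expect_error(giniImpurity(c(0, 0)), "empty node")
  expect_error(giniImpurity(c(-1, 2)), "negative")
})

test_that("best splits match degenerate closed-form cases", {
  # one candidate perfectly separates the classes at g <= 0
  gm <- gmat(cbind(c(0, 0, 2, 2), c(1, 1, 1, 1)))
  y <- PhenotypeVector(c(0L, 0L, 1L, 1L), classNames = c("0", "1"))
  block <- partitionVariants(gm, 1L)[[1]]
  sc <- bestSplit(gm, block, 1:4, y, 1:2)
  expect_identical(sc@variantIndex, 1L)
  expect_identical(sc@threshold, 0L)
  expect_equal(sc@gain, giniImpurity(c(2, 2)))
  expect_identical(c(sc@leftSize, sc@rightSize), c(2L, 2L))

  # a constant candidate contributes no valid split
  expect_null(bestSplit(gm, block, 1:4, y, 2L))
  # candidates must be owned by the evaluating block
  b2 <- partitionVariants(gm, 2L)[[1]]
  expect_error(bestSplit(gm, b2, 1:4, y, 2L), "outside the block")
})

test_that("aggregation takes the argmax with deterministic tie-breaks", {
  sc <- function(v, thr, gain) new("SplitCandidate", variantIndex = v,
                                   threshold = thr, gain = gain,
                                   leftSize = 1L, rightSize = 1L)
  expect_identical(
    aggregateLocalBests(list(sc(1L, 0L, 0.3), sc(5L, 1L, 0.5), NULL)),
    sc(5L, 1L, 0.5))
  # equal gain: lower variant index wins; equal variant: lower threshold
  expect_identical(
    aggregateLocalBests(list(sc(7L, 0L, 0.4), sc(3L, 1L, 0.4))),
    sc(3L, 1L, 0.4))
  expect_null(aggregateLocalBests(list(NULL, NULL)))
})

test_that("chosen splits equal exhaustive enumeration on random nodes", {
  set.seed(123)
  for (case in 1:250) {
    nS <- sample(2:12, 1)
    nV <- sample(1:5, 1)
    K <- sample(2:3, 1)
    gm <- gmat(matrix(sample(0:2, nS * nV, TRUE), nS, nV))
    y <- PhenotypeVector(sample.int(K, nS, TRUE) - 1L,
                         classNames = as.character(seq_len(K) - 1L))
    idx <- sample.int(nS, nS, replace = TRUE)  # bootstrap-like multiset
    cand <- sort(sample.int(nV, sample(nV, 1)))
    got <- partitionedBest(gm, idx, y, cand, sample(nV, 1))
    want <- bruteForceBest(genotypes(gm), idx, classCodes(y), cand)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_identical(got@variantIndex, as.integer(want[1]))
      expect_identical(got@threshold, as.integer(want[2]))
      expect_equal(got@gain, want[3], tolerance = 1e-12)
    }
  }
})

test_that("tree growth honors stop rules and split semantics", {
  set.seed(77)
  nS <- 200L
  g <- matrix(sample(0:2, nS * 20, TRUE), nS)
  y <- PhenotypeVector(as.integer(g[, 7] >= 1), classNames = c("0", "1"))
  gm <- GenotypeMatrix(g)

  # linearly separable single-variant signal, all variants evaluated:
  # a depth-1 stump on the signal variant
  tr <- growTree(gm, y, ForestParams(nTree = 1, mTry = 20, seed = 1),
                 treeIndex = 1, bootstrap = FALSE)$nodes
  expect_identical(nrow(tr), 3L)
  expect_identical(tr$variant[1], 7L)
  expect_identical(tr$threshold[1], 0L)
  expect_identical(max(tr$depth), 1L)

  # depth and node-size limits are never violated; children sum to parents
  yHard <- PhenotypeVector(sample(0:1, nS, TRUE), classNames = c("0", "1"))
  tr2 <- growTree(gm, yHard, ForestParams(nTree = 1, mTry = 5, maxD = 3,
                                          minNS = 50, seed = 2))$nodes
  expect_lte(max(tr2$depth), 3L)
  splits <- which(!is.na(tr2$variant))
  expect_true(all(tr2$size[splits] >= 50L))
  expect_identical(tr2$size[tr2$left[splits]] + tr2$size[tr2$right[splits]],
                   tr2$size[splits])
  # gain conservation: imp(parent)*n >= imp(L)*nL + imp(R)*nR strictly here
  expect_true(all(tr2$gain[splits] > 0))
})

test_that("trained models are invariant to partitioning and batching", {
  gm <- genFeatures(100, 50, seed = 21)
  sim <- genLabel(gm, LabelSimSpec(kCausal = 3, gvf = 0.1, seed = 21))
  base <- trainForest(gm, sim$phenotype,
                      ForestParams(nTree = 12, rbs = 12L, seed = 5))
  for (cfg in list(c(4L, 3L), c(16L, 1L), c(1L, 5L))) {
    alt <- trainForest(gm, sim$phenotype,
                       ForestParams(nTree = 12, rbs = cfg[2], seed = 5),
                       nBlocks = cfg[1])
    expect_identical(alt@trees, base@trees)
    expect_identical(alt@inBag, base@inBag)
    expect_identical(alt@importance, base@importance)
    expect_identical(alt@oobError, base@oobError)
  }
  # mTry = 1 still yields a valid forest of random splits
  tiny <- trainForest(gm, sim$phenotype,
                      ForestParams(nTree = 5, mTry = 1, seed = 5))
  expect_true(all(tiny@importance >= 0))
})

test_that("a single unbagged tree is a deterministic decision tree", {
  gm <- genFeatures(80, 15, seed = 31)
  sim <- genLabel(gm, LabelSimSpec(kCausal = 2, gm = 0, gs = 0, seed = 31))
  p <- ForestParams(nTree = 1, mTry = 15, seed = 3)
  t1 <- growTree(gm, sim$phenotype, p, 1, bootstrap = FALSE)
  t2 <- growTree(gm, sim$phenotype, p, 1, nBlocks = 5, bootstrap = FALSE)
  expect_identical(t1, t2)
  # an unlimited deterministic tree classifies its training data perfectly
  pred <- ForestGWAS:::.predictTree(t1$nodes, genotypes(gm), seq_len(80))
  expect_identical(pred, classCodes(sim$phenotype))
})

test_that("importance follows the size-weighted mean-gain formula", {
  # single unbagged stump: score = (n/nS) * gain / nTree = parent impurity
  gm <- gmat(cbind(c(0, 0, 2, 2), c(1, 0, 1, 0)))
  y <- PhenotypeVector(c(0L, 0L, 1L, 1L), classNames = c("0", "1"))
  fit <- trainForest(gm, y, ForestParams(nTree = 1, mTry = 2, seed = 1),
                     bootstrap = FALSE)
  expect_equal(unname(importanceScores(fit)), c(0.5, 0))
  expect_equal(unname(importanceScores(fit, weighted = FALSE)), c(0.5, 0))

  # variants never chosen as best split score exactly zero
  gm2 <- genFeatures(100, 30, seed = 41)
  sim <- genLabel(gm2, LabelSimSpec(kCausal = 1, gm = 0, gs = 0, seed = 41))
  fit2 <- trainForest(gm2, sim$phenotype, ForestParams(nTree = 10, seed = 2))
  used <- unique(unlist(lapply(fit2@trees, function(tr)
    tr$variant[!is.na(tr$variant)])))
  expect_true(all(importanceScores(fit2)[-used] == 0))
  # manual recomputation from the stored trees matches the slot
  manual <- numeric(30)
  for (tr in fit2@trees) {
    s <- which(!is.na(tr$variant))
    for (i in s) manual[tr$variant[i]] <- manual[tr$variant[i]] +
        tr$size[i] / 100 * tr$gain[i]
  }
  expect_equal(unname(importanceScores(fit2)), manual / 10)
})

test_that("a planted causal variant tops the importance ranking", {
  hits <- 0L
  nSeeds <- 20L
  for (s in seq_len(nSeeds)) {
    gm <- genFeatures(1000, 200, seed = 5000 + s)
    sim <- genLabel(gm, LabelSimSpec(kCausal = 1, gm = 0, gs = 0,
                                     seed = 5000 + s))
    fit <- trainForest(gm, sim$phenotype,
                       ForestParams(nTree = 200, maxD = 15, minNS = 50,
                                    seed = s))
    if (which.max(importanceScores(fit)) == truthVariants(sim$truth))
      hits <- hits + 1L
  }
  expect_gte(hits / nSeeds, 0.95)
})

test_that("forest ranking agrees with an independent implementation", {
  skip_if_not_installed("randomForest")
  gm <- genFeatures(300, 40, seed = 61)
  sim <- genLabel(gm, LabelSimSpec(kCausal = 2, gm = 0, gs = 0, seed = 61))
  fit <- trainForest(gm, sim$phenotype, ForestParams(nTree = 100, seed = 6))
  rf <- randomForest::randomForest(genotypes(gm),
                                   factor(classCodes(sim$phenotype)),
                                   ntree = 100)
  tv <- truthVariants(sim$truth)
  expect_setequal(order(-importanceScores(fit))[1:2], tv)
  expect_setequal(order(-rf$importance[, 1])[1:2], tv)
})

test_that("out-of-bag error is recomputable and zero for a learnable rule", {
  set.seed(71)
  g <- matrix(sample(0:2, 150 * 10, TRUE), 150)
  gm <- GenotypeMatrix(g)
  y <- PhenotypeVector(as.integer(g[, 3] >= 1), classNames = c("0", "1"))
  fit <- trainForest(gm, y, ForestParams(nTree = 60, mTry = 10, seed = 7))
  expect_identical(oobError(fit), 0)
  expect_identical(oobError(fit, gm, y), fit@oobError)
})

test_that("complexity and runtime models reproduce their formulas", {
  expect_identical(opCount(1e4, 100, 1e7, 1e4), 1e17)
  expect_identical(opCount(1, 3, 5, 7), 105)
  expect_identical(opCount(1, 1, 1, 1), 1)
  expect_identical(expectedRuntime(100, 2, 1000), 2100)
  expect_identical(expectedRuntime(7, 0, 500), 7)
  expect_identical(expectedRuntime(7, 3, 0), 7)
})

test_that("model statistics and JSON export describe the trees faithfully", {
  gm <- genFeatures(120, 20, seed = 81)
  sim <- genLabel(gm, LabelSimSpec(kCausal = 1, gm = 0, gs = 0, seed = 81))
  # depth-1 stumps: average depth and split-node count are both 1
  stumps <- trainForest(gm, sim$phenotype,
                        ForestParams(nTree = 10, mTry = 20, maxD = 1,
                                     seed = 8))
  expect_equal(unname(modelStats(stumps)), c(1, 1))

  fit <- trainForest(gm, sim$phenotype, ForestParams(nTree = 5, seed = 8))
  path <- withr::local_tempfile(fileext = ".json")
  exportModelJSON(fit, path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_length(obj$trees, 5L)
  expect_equal(unlist(obj$treeNodeCounts), fit@treeNodeCounts)
  # recompute each tree's maximum leaf depth from the nested export
  depthOf <- function(node, d = 0) {
    if (!is.null(node$leafClass)) return(d)
    max(depthOf(node$left, d + 1), depthOf(node$right, d + 1))
  }
  expect_equal(vapply(obj$trees, depthOf, 0), fit@treeDepths)

  csv <- withr::local_tempfile(fileext = ".csv")
  df <- writeImportanceCSV(fit, csv)
  expect_identical(df$rank, seq_len(20L))
  expect_false(is.unsorted(rev(df$importance)))
})
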
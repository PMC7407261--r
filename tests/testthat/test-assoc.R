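test_that("Wald p-values agree with the reference IRLS fitter", {
  set.seed(91)
  gm <- genFeatures(300, 15, seed = 91)
  eta <- 0.8 * genotypes(gm)[, 4] - 0.5
  y <- PhenotypeVector(rbinom(300, 1, plogis(eta)), classNames = c("0", "1"))
  covars <- cbind(rnorm(300), rnorm(300))
  pv <- lrWald(gm, y, covars)
  for (j in c(1, 4, 9)) {
    fit <- glm(classCodes(y) ~ covars + genotypes(gm)[, j],
               family = binomial(),
               control = glm.control(epsilon = 1e-12))
    pGlm <- summary(fit)$coefficients[4, 4]
    # compare on the log scale: tail p-values amplify tiny z differences
    expect_equal(log(unname(pv[j])), log(pGlm), tolerance = 1e-4)
  }
  expect_lt(pv[4], 1e-4)  # the causal variant is found
})

test_that("separated and degenerate variants are flagged missing", {
  set.seed(95)
  g <- cbind(c(rep(0L, 20), rep(2L, 20)), rep(1L, 40),
             sample(0:2, 40, TRUE))
  gm <- GenotypeMatrix(g)
  y <- PhenotypeVector(c(rep(0L, 20), rep(1L, 20)), classNames = c("0", "1"))
  expect_message(pv <- lrWald(gm, y), "without a converged Wald fit")
  expect_true(is.na(pv[1]))  # perfect separation: divergent MLE
  expect_true(is.na(pv[2]))  # constant genotype: singular information
  expect_true(1 %in% attr(pv, "failed"))
})

test_that("parity members are invisible to the regression baseline", {
  maf <- carrierMAF(0.5)
  ok <- 0L
  for (s in 1:10) {
    gm <- genFeatures(2000, 10, mafRange = c(maf, maf), seed = 300 + s)
    sim <- genEpistaticLabel(gm, EpistasisSpec(c("2" = 1), noiseSd = 0,
                                               seed = 300 + s))
    pv <- lrWald(gm, sim$phenotype)
    if (all(pv[sim$truth@variables[[1]]$members] > 0.01)) ok <- ok + 1L
  }
  expect_gte(ok / 10, 0.9)
})

test_that("principal components capture population structure deterministically", {
  set.seed(101)
  # two sample blocks with shifted allele frequencies
  gA <- matrix(rbinom(100 * 60, 2, 0.15), 100)
  gB <- matrix(rbinom(100 * 60, 2, 0.45), 100)
  gm <- GenotypeMatrix(rbind(gA, gB))
  pcs <- pcaCovariates(gm, 2)
  groups <- rep(c("A", "B"), each = 100)
  expect_gt(abs(mean(pcs[groups == "A", 1]) - mean(pcs[groups == "B", 1])),
            2 * sd(pcs[, 1]) / sqrt(100))
  # loadings are orthonormal and the sign convention is deterministic
  rot <- attr(pcs, "rotation")
  expect_equal(crossprod(rot), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(vapply(1:2, function(i)
    rot[which.max(abs(rot[, i])), i] > 0, TRUE)))
  expect_identical(pcs, pcaCovariates(gm, 2))

  expect_identical(ncol(pcaCovariates(gm, 0)), 0L)
  expect_error(pcaCovariates(gm, 70), "k too large")
})

test_that("ranking is a deterministic total order with missing scores last", {
  r <- rankVariants(c(a = 0.3, b = 0.9, c = 0.3, d = NA), method = "imp")
  expect_identical(r@index, c(2L, 1L, 3L, 4L))
  expect_identical(r@ids, c("b", "a", "c", "d"))
  expect_identical(rankVariants(numeric(0))@index, integer(0))
  # ranking p ascending equals ranking -log10(p) descending
  p <- c(0.2, 1e-8, NA, 0.05)
  expect_identical(rankVariants(p, decreasing = FALSE)@index,
                   rankVariants(-log10(p), decreasing = TRUE)@index)
  # identical scores fall back to index order
  expect_identical(rankVariants(rep(1, 4))@index, 1:4)
})

test_that("recovery counts truth-variants in growing rank prefixes", {
  truth <- new("TruthSet",
               variables = lapply(c(3L, 8L, 11L, 17L), function(v)
                 list(order = 1L, members = v, weight = 1)),
               truthVariants = c(3L, 8L, 11L, 17L), metadata = list())
  scores <- numeric(40)
  scores[c(3, 8)] <- c(5, 4)       # two truth-variants lead the ranking
  scores[setdiff(1:40, truth@truthVariants)] <- runif(36)
  r <- rankVariants(scores)
  rec <- tvRecovery(r, truth)
  expect_identical(unname(rec[["1t"]]), 0.5)   # 2 of 4 in the top 4
  expect_true(all(diff(rec) >= 0))             # non-decreasing in r

  # all truth-variants first: recovery 1 already at r = t
  perfect <- rankVariants(replace(numeric(40), truth@truthVariants, 9))
  expect_identical(unname(tvRecovery(perfect, truth)[["1t"]]), 1)
  # truth disjoint from the whole top-10t prefix
  none <- rankVariants(replace(rep(1, 400), truth@truthVariants, 0))
  expect_identical(unname(tvRecovery(none, truth)), rep(0, 4))
})

test_that("gamma scores measure proxy detection through correlation", {
  set.seed(111)
  g <- matrix(sample(0:2, 100 * 20, TRUE), 100)
  g[, 5] <- g[, 2]          # variant 5 duplicates truth-variant 2
  g[, 9] <- 1L              # constant column
  gm <- GenotypeMatrix(g)
  truth <- new("TruthSet",
               variables = list(list(order = 1L, members = 2L, weight = 1)),
               truthVariants = 2L, metadata = list())
  # the truth-variant itself inside the top-10t prefix
  rSelf <- rankVariants(replace(numeric(20), 2, 1))
  expect_identical(unname(gammaScores(rSelf, truth, gm)), 1)
  # excluded itself, but a duplicate column is a perfect proxy
  sc <- runif(20); sc[2] <- NA; sc[5] <- 2
  expect_identical(unname(gammaScores(rankVariants(sc), truth, gm)), 1)
  # |Pearson r| is invariant to scaling of the proxy column
  gmScaled <- GenotypeMatrix(cbind(g[, 1:4], 2L * g[, 5], g[, 6:20]),
                             ordinalMax = 4L)
  expect_equal(gammaScores(rankVariants(sc), truth, gmScaled),
               gammaScores(rankVariants(sc), truth, gm), tolerance = 1e-12)

  # independent top variants: gamma stays small (null extreme value)
  gm2 <- genFeatures(2000, 60, seed = 112)
  truth2 <- new("TruthSet",
                variables = lapply(51:55, function(v)
                  list(order = 1L, members = v, weight = 1)),
                truthVariants = 51:55, metadata = list())
  rNull <- rankVariants(replace(rep(1, 60), 51:60, 0))  # top 50 independent
  expect_lt(max(gammaScores(rNull, truth2, gm2)), 0.1)
})

test_that("exclusive detection applies strict dual thresholds", {
  expect_identical(exclusiveDetection(0.9, 0.4), c(aOnly = 1L, bOnly = 0L))
  expect_identical(exclusiveDetection(0.9, 0.9), c(aOnly = 0L, bOnly = 0L))
  expect_identical(exclusiveDetection(0.7, 0.4), c(aOnly = 0L, bOnly = 0L))
  expect_identical(
    exclusiveDetection(c(0.9, 0.2, 0.8), c(0.1, 0.9, 0.6)),
    c(aOnly = 1L, bOnly = 1L))
  expect_error(exclusiveDetection(c(a = 1), c(b = 1)), "same truth-variants")
})

test_that("evaluation reports round-trip recovery, gamma and exclusives", {
  gm <- genFeatures(400, 80, seed = 121)
  sim <- genLabel(gm, LabelSimSpec(kCausal = 4, gm = 0, gs = 0, seed = 121))
  fit <- trainForest(gm, sim$phenotype, ForestParams(nTree = 60, seed = 12))
  pv <- lrWald(gm, sim$phenotype)
  report <- evaluateRankings(
    list(RF = rankVariants(importanceScores(fit), method = "RF"),
         LR = rankVariants(pv, decreasing = FALSE, method = "LR")),
    sim$truth, gm)
  expect_identical(dim(report@recovery), c(2L, 4L))
  expect_true(all(report@recovery >= 0 & report@recovery <= 1))
  expect_true(all(report@gamma >= 0 & report@gamma <= 1))
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  writeEvalReport(report, csv, json)
  expect_identical(nrow(read.csv(csv)), 4L)
  obj <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(unlist(obj$recovery$RF), report@recovery["RF", ],
               tolerance = 1e-12)
})
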
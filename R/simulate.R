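#' @include AllClasses.R
NULL

#' LabelSimSpec: additive phenotype simulation settings
#'
#' Settings for the additive-plus-noise label generator
#' (\code{\link{genLabel}}): a handful of causal variants with fixed weights,
#' plus a fraction of "noise variants" whose weights are drawn from a normal
#' distribution, making them weak confounders.
#'
#' @slot kCausal number of causal variants (default 5).
#' @slot weights per-causal contribution (default all 1.0).
#' @slot gm mean of the noise-variant weight distribution.
#' @slot gs standard deviation of the noise-variant weight distribution.
#' @slot gvf fraction of variants acting as noise variants (\code{gvf = 100/nV}
#'   selects exactly 100 of them).
#' @slot seed RNG seed.
#' @export
setClass("LabelSimSpec",
         representation(kCausal = "integer", weights = "numeric",
                        gm = "numeric", gs = "numeric", gvf = "numeric",
                        seed = "integer"))

setValidity("LabelSimSpec", function(object) {
  msg <- character(0)
  if (object@kCausal < 1L) msg <- c(msg, "kCausal must be >= 1")
  if (length(object@weights) != object@kCausal)
    msg <- c(msg, "weights length must equal kCausal")
  if (object@gvf < 0 || object@gvf > 1) msg <- c(msg, "need 0 <= gvf <= 1")
  if (object@gs < 0) msg <- c(msg, "gs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelSimSpec
#'
#' Defaults follow the standard simulation design: 5 causal variants with
#' equal weights 1.0 and noise weights drawn from Normal(0.5, 0.5).
#'
#' @param kCausal number of causal variants.
#' @param weights per-causal weights (recycled scalar allowed).
#' @param gm,gs mean and sd of the noise-variant weights.
#' @param gvf fraction of variants acting as noise variants.
#' @param seed RNG seed.
#' @return A \linkS4class{LabelSimSpec}.
#' @export
LabelSimSpec <- function(kCausal = 5L, weights = rep(1, kCausal),
                         gm = 0.5, gs = 0.5, gvf = 0, seed = 1L) {
  if (length(weights) == 1L) weights <- rep(weights, kCausal)
  new("LabelSimSpec", kCausal = as.integer(kCausal),
      weights = as.numeric(weights), gm = as.numeric(gm),
      gs = as.numeric(gs), gvf = as.numeric(gvf), seed = as.integer(seed))
}

#' EpistasisSpec: polygenic-epistatic phenotype simulation settings
#'
#' Settings for \code{\link{genEpistaticLabel}}.  The phenotype is driven by
#' n-way truth-variables for n in 1..5: a 1-way variable is a single variant,
#' an n-way variable is the parity (XOR) of the dominance indicators
#' \code{[g >= 1]} of n variants, so for n >= 2 and carrier probability 0.5
#' each member has no marginal association by construction.
#'
#' @slot countsByOrder integer vector of length 5: the number of n-way
#'   truth-variables for n = 1..5.
#' @slot carrierProb probability that a variant's dominance indicator is 1;
#'   determined by the genotype allele frequency (see \code{\link{carrierMAF}}),
#'   recorded here as the design value.
#' @slot noiseSd standard deviation of the liability noise.
#' @slot seed RNG seed.
#' @export
setClass("EpistasisSpec",
         representation(countsByOrder = "integer", carrierProb = "numeric",
                        noiseSd = "numeric", seed = "integer"))

setValidity("EpistasisSpec", function(object) {
  msg <- character(0)
  if (length(object@countsByOrder) != 5L)
    msg <- c(msg, "countsByOrder must have length 5 (orders 1..5)")
  if (any(object@countsByOrder < 0L))
    msg <- c(msg, "counts must be >= 0")
  if (object@carrierProb <= 0 || object@carrierProb >= 1)
    msg <- c(msg, "carrierProb must lie in (0, 1)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an EpistasisSpec
#'
#' @param countsByOrder number of n-way truth-variables for n = 1..5; either
#'   a length-5 vector or a named vector like \code{c("2" = 2, "3" = 2)}
#'   (unnamed orders default to 0).
#' @param carrierProb design carrier probability (default 0.5, the value that
#'   makes parity members marginally null).
#' @param noiseSd liability noise sd.  The default 0.5 corresponds to a
#'   strongly genetic trait (unit-weighted variables each contribute
#'   variance 0.25); set 0 for a noiseless liability.
#' @param seed RNG seed.
#' @return An \linkS4class{EpistasisSpec}.
#' @examples
#' truthCounts(EpistasisSpec(c("2" = 2, "3" = 2, "4" = 2, "5" = 2)))
#' @export
EpistasisSpec <- function(countsByOrder, carrierProb = 0.5, noiseSd = 0.5,
                          seed = 1L) {
  if (!is.null(names(countsByOrder))) {
    full <- integer(5L)
    ord <- as.integer(names(countsByOrder))
    if (anyNA(ord) || any(ord < 1L) || any(ord > 5L))
      stop("countsByOrder names must be orders 1..5")
    full[ord] <- as.integer(countsByOrder)
    countsByOrder <- full
  }
  new("EpistasisSpec", countsByOrder = as.integer(countsByOrder),
      carrierProb = as.numeric(carrierProb), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

#' Truth-variable and truth-variant totals of an epistasis design
#'
#' @param spec an \linkS4class{EpistasisSpec}.
#' @return Named integer vector \code{c(nVariables, nVariants)}:
#'   \code{sum(counts)} truth-variables and \code{sum(n * counts[n])}
#'   distinct truth-variants (variables are disjoint, so members never
#'   overlap).
#' @examples
#' truthCounts(EpistasisSpec(c(50L, 25L, 17L, 13L, 10L)))  # 115, 253
#' @export
truthCounts <- function(spec) {
  stopifnot(is(spec, "EpistasisSpec"))
  cnt <- spec@countsByOrder
  c(nVariables = sum(cnt), nVariants = sum(seq_len(5L) * cnt))
}

#' Minor-allele frequency giving a target carrier probability
#'
#' For genotypes drawn Binomial(2, f), the dominance indicator
#' \code{[g >= 1]} has probability \code{1 - (1 - f)^2}; inverting gives the
#' allele frequency at which parity truth-variables have marginally null
#' members (\code{carrierMAF(0.5)} is about 0.293).
#'
#' @param p target carrier probability in (0, 1).
#' @return Allele frequency \code{1 - sqrt(1 - p)}.
#' @export
carrierMAF <- function(p) {
  stopifnot(p > 0, p < 1)
  1 - sqrt(1 - p)
}

#' Simulate a random genotype matrix
#'
#' Per-variant allele frequencies are drawn uniformly from \code{mafRange};
#' genotypes are then independent Binomial(2, freq) allele counts per sample.
#' Deterministic for a fixed seed.
#'
#' @param nS,nV sample and variant counts (>= 1).
#' @param mafRange allele-frequency interval, a sub-interval of (0, 0.5];
#'   a degenerate interval \code{c(f, f)} fixes the frequency.
#' @param seed RNG seed.
#' @return A \linkS4class{GenotypeMatrix} with ids \code{V1..VnV} /
#'   \code{S1..SnS}.
#' @examples
#' gm <- genFeatures(100, 20, mafRange = c(0.1, 0.5), seed = 42)
#' @export
genFeatures <- function(nS, nV, mafRange = c(0.05, 0.5), seed = 1L) {
  nS <- as.integer(nS); nV <- as.integer(nV)
  if (nS < 1L || nV < 1L) stop("need nS >= 1 and nV >= 1")
  if (length(mafRange) != 2L || mafRange[1L] <= 0 || mafRange[2L] > 0.5 ||
      mafRange[1L] > mafRange[2L])
    stop("mafRange must be an interval within (0, 0.5]")
  set.seed(as.integer(seed))
  freq <- runif(nV, mafRange[1L], mafRange[2L])
  g <- matrix(rbinom(nS * nV, 2L, rep(freq, each = nS)), nrow = nS)
  GenotypeMatrix(g)
}

## Median-threshold dichotomization shared by both label generators,
## implemented as a rank threshold: the ceiling(n/2) samples with the highest
## liability are cases (ties broken by sample index).  For a continuous
## liability this coincides with `L >= median(L)` almost surely; for discrete
## liabilities it keeps the classes balanced to within one sample, which the
## plain median rule cannot guarantee under ties.
.dichotomize <- function(liability) {
  n <- length(liability)
  labels <- integer(n)
  labels[order(-liability, seq_len(n))[seq_len(ceiling(n / 2))]] <- 1L
  labels
}

#' Simulate an additive phenotype with noise variants
#'
#' Chooses \code{kCausal} causal variants uniformly without replacement and
#' \code{round(gvf * nV)} noise variants from the remainder; each noise
#' variant gets one weight drawn from Normal(gm, gs) (per variant, not per
#' sample, so noise variants carry weak but real association).  The liability
#' of sample j is
#' \deqn{L_j = \sum_i w_i g_{ij} + \sum_k \epsilon_k g_{kj}}
#' over causal variants i and noise variants k, and the binary label
#' dichotomizes the liability at its median (rank-based, so the classes are
#' balanced to within one sample even when liabilities tie; for a continuous
#' liability this is exactly \code{L >= median(L)}).  Only the causal
#' variants enter the
#' truth set (as 1-way variables); noise variants are recorded in the truth
#' set's metadata but are not truth-variants.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param spec a \linkS4class{LabelSimSpec}.
#' @return \code{list(phenotype = PhenotypeVector, truth = TruthSet)}.
#' @examples
#' gm <- genFeatures(200, 50, seed = 7)
#' sim <- genLabel(gm, LabelSimSpec(kCausal = 5, gvf = 10/50, seed = 7))
#' truthVariants(sim$truth)
#' @export
genLabel <- function(x, spec) {
  stopifnot(is(x, "GenotypeMatrix"), is(spec, "LabelSimSpec"))
  nV <- nVariants(x)
  nNoise <- round(spec@gvf * nV)
  if (spec@kCausal + nNoise > nV)
    stop("kCausal + round(gvf * nV) exceeds nV")
  set.seed(spec@seed)
  causal <- sample.int(nV, spec@kCausal)
  noise <- if (nNoise > 0L)
    sample(setdiff(seq_len(nV), causal), nNoise) else integer(0)
  eps <- rnorm(nNoise, spec@gm, spec@gs)
  g <- genotypes(x)
  liability <- as.numeric(g[, causal, drop = FALSE] %*% spec@weights)
  if (nNoise > 0L)
    liability <- liability +
      as.numeric(g[, noise, drop = FALSE] %*% eps)
  labels <- .dichotomize(liability)
  truth <- new("TruthSet",
               variables = lapply(seq_along(causal), function(i)
                 list(order = 1L, members = causal[i],
                      weight = spec@weights[i])),
               truthVariants = sort(causal),
               metadata = list(model = "additive", gm = spec@gm,
                               gs = spec@gs, gvf = spec@gvf,
                               noiseVariants = sort(noise),
                               noiseWeights = eps[order(noise)],
                               seed = spec@seed))
  list(phenotype = new("PhenotypeVector", codes = labels,
                       classNames = c("0", "1")),
       truth = truth)
}

#' Simulate a polygenic-epistatic phenotype
#'
#' Samples pairwise-disjoint variant sets for the requested n-way
#' truth-variables.  A variable's value for a sample is the parity (XOR) of
#' the dominance indicators \code{d_i = [g_i >= 1]} over its members (n = 1
#' reduces to \code{d_1}).  The liability is the unit-weighted sum of the
#' variable values plus Normal(0, noiseSd) noise; the binary label
#' dichotomizes the liability at its median (rank-based, balanced to within
#' one sample).  For n >= 2 and carrier probability 0.5
#' each member's marginal association with its variable value is null by
#' construction — the signal only exists in combination.
#'
#' @param x a \linkS4class{GenotypeMatrix}; for exact marginal nullity its
#'   allele frequencies should give the spec's carrier probability (see
#'   \code{\link{carrierMAF}}).
#' @param spec an \linkS4class{EpistasisSpec}.
#' @return \code{list(phenotype = PhenotypeVector, truth = TruthSet)}.
#' @examples
#' gm <- genFeatures(500, 100, mafRange = rep(carrierMAF(0.5), 2), seed = 3)
#' sim <- genEpistaticLabel(gm, EpistasisSpec(c("2" = 5), seed = 3))
#' @export
genEpistaticLabel <- function(x, spec) {
  stopifnot(is(x, "GenotypeMatrix"), is(spec, "EpistasisSpec"))
  nV <- nVariants(x)
  tc <- truthCounts(spec)
  if (tc[["nVariants"]] > nV)
    stop("spec needs ", tc[["nVariants"]], " distinct variants but nV = ", nV)
  set.seed(spec@seed)
  members <- sample.int(nV, tc[["nVariants"]])
  d <- genotypes(x) >= 1L
  variables <- vector("list", tc[["nVariables"]])
  value <- matrix(0L, nSamples(x), tc[["nVariables"]])
  used <- 0L; vi <- 0L
  for (ord in 1:5) {
    for (k in seq_len(spec@countsByOrder[ord])) {
      vi <- vi + 1L
      mem <- members[used + seq_len(ord)]
      used <- used + ord
      variables[[vi]] <- list(order = ord, members = sort(mem), weight = 1)
      value[, vi] <- rowSums(d[, mem, drop = FALSE]) %% 2L
    }
  }
  liability <- rowSums(value) + rnorm(nSamples(x), 0, spec@noiseSd)
  labels <- .dichotomize(liability)
  truth <- new("TruthSet", variables = variables,
               truthVariants = sort(members),
               metadata = list(model = "parity",
                               carrierProb = spec@carrierProb,
                               noiseSd = spec@noiseSd, seed = spec@seed))
  list(phenotype = new("PhenotypeVector", codes = labels,
                       classNames = c("0", "1")),
       truth = truth)
}

#' Write a truth set as JSON
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param path output path.
#' @param variantIds optional character vector mapping indices to ids (ids
#'   are stored alongside the indices when given).
#' @return Invisibly, \code{path}.
#' @export
writeTruthJSON <- function(truth, path, variantIds = NULL) {
  stopifnot(is(truth, "TruthSet"))
  vars <- lapply(truth@variables, function(v) {
    out <- list(order = v$order, members = as.integer(v$members),
                weight = v$weight)
    if (!is.null(variantIds)) out$memberIds <- variantIds[v$members]
    out
  })
  obj <- list(variables = vars,
              truthVariants = as.integer(truth@truthVariants),
              metadata = truth@metadata)
  if (!is.null(variantIds))
    obj$truthVariantIds <- variantIds[truth@truthVariants]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a truth set from JSON
#'
#' @param path path written by \code{\link{writeTruthJSON}}.
#' @return A \linkS4class{TruthSet}.
#' @export
readTruthJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  variables <- lapply(obj$variables, function(v)
    list(order = as.integer(v$order), members = as.integer(v$members),
         weight = as.numeric(v$weight)))
  new("TruthSet", variables = variables,
      truthVariants = sort(as.integer(obj$truthVariants)),
      metadata = if (is.null(obj$metadata)) list() else obj$metadata)
}
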
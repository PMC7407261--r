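#' @include AllClasses.R
NULL

#' Per-variant logistic-regression Wald test
#'
#' The single-variant association baseline: for every variant, a logistic
#' regression of the binary label on \code{[intercept, covariates, genotype]}
#' is fitted by Newton-Raphson (at most 25 iterations, converged when the
#' largest coefficient change drops below 1e-8), and the Wald p-value is
#' taken from the genotype coefficient's z statistic.  Variants whose fit
#' does not converge (e.g. perfect separation, where the MLE diverges) or
#' whose information matrix is singular (e.g. constant genotype) get
#' \code{NA} and are ranked last downstream.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param y a binary \linkS4class{PhenotypeVector}.
#' @param covariates optional numeric matrix of per-sample covariates
#'   (e.g. principal components from \code{\link{pcaCovariates}}); may have
#'   zero columns.
#' @return Named numeric vector of p-values (names are variant ids), with
#'   \code{NA} for failed fits; the failed variant indices are attached as
#'   attribute \code{"failed"}.
#' @export
lrWald <- function(x, y, covariates = NULL) {
  stopifnot(is(x, "GenotypeMatrix"), is(y, "PhenotypeVector"))
  codes <- classCodes(y)
  if (length(unique(codes)) != 2L)
    stop("the Wald baseline requires binary labels")
  nS <- nSamples(x)
  if (is.null(covariates))
    covariates <- matrix(numeric(0), nS, 0L)
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != nS)
    stop("covariates must have one row per sample")
  G <- genotypes(x)
  X0 <- cbind(1, covariates)
  p <- ncol(X0) + 1L
  yy <- as.numeric(codes)
  pv <- rep(NA_real_, nVariants(x))
  for (j in seq_len(nVariants(x))) {
    Xj <- cbind(X0, G[, j])
    beta <- numeric(p)
    conv <- FALSE
    H <- NULL
    for (it in seq_len(25L)) {
      mu <- plogis(as.numeric(Xj %*% beta))
      w <- mu * (1 - mu)
      H <- crossprod(Xj, Xj * w)
      delta <- tryCatch(solve(H, crossprod(Xj, yy - mu)),
                        error = function(e) NULL)
      if (is.null(delta)) break
      beta <- beta + as.numeric(delta)
      if (max(abs(delta)) < 1e-8) { conv <- TRUE; break }
    }
    if (!conv) next
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(cov) || cov[p, p] <= 0) next
    z <- beta[p] / sqrt(cov[p, p])
    pv[j] <- 2 * pnorm(-abs(z))
  }
  names(pv) <- variantIds(x)
  failed <- which(is.na(pv))
  if (length(failed))
    message(length(failed), " variant(s) without a converged Wald fit ",
            "(separation or degenerate genotype); recorded as missing")
  attr(pv, "failed") <- failed
  pv
}

#' Principal-component covariates from the genotype matrix
#'
#' Top-k principal components of the column-standardized genotype matrix
#' (constant columns are dropped before standardizing), the usual population
#' -structure covariates for the regression baseline.  Each component's sign
#' is fixed so its largest-magnitude loading is positive, making the result
#' deterministic.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param k number of components, \code{0 <= k < min(nS, nV)}; \code{k = 0}
#'   returns a zero-column matrix (intercept-only baseline).
#' @param maxVariants optional cap: when set and smaller than the number of
#'   usable variants, a seed-controlled subsample of columns is used
#'   (a throughput knob for very wide matrices; off by default).
#' @param seed seed for the subsample draw.
#' @return \code{nS x k} numeric matrix of component scores, with the
#'   loadings attached as attribute \code{"rotation"}.
#' @export
pcaCovariates <- function(x, k, maxVariants = NULL, seed = 1L) {
  stopifnot(is(x, "GenotypeMatrix"), k >= 0)
  nS <- nSamples(x)
  if (k == 0L)
    return(matrix(numeric(0), nS, 0L))
  G <- genotypes(x)
  sds <- apply(G, 2L, sd)
  keep <- which(sds > 0)
  if (!is.null(maxVariants) && maxVariants < length(keep)) {
    set.seed(as.integer(seed))
    keep <- sort(sample(keep, maxVariants))
  }
  if (k >= min(nS, length(keep)))
    stop("k too large: need k < min(nS, usable nV)")
  Z <- scale(G[, keep, drop = FALSE])
  sv <- svd(Z, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(i) {
    v <- sv$v[, i]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2L, flip, `*`)
  rotation <- sweep(sv$v[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  rownames(rotation) <- variantIds(x)[keep]
  colnames(scores) <- colnames(rotation) <- paste0("PC", seq_len(k))
  attr(scores, "rotation") <- rotation
  scores
}

#' Rank variants by an association score
#'
#' Deterministic total order: by score (descending for importance, ascending
#' for p-values), ties broken by variant index ascending, missing scores
#' last.
#'
#' @param scores one score per variant; \code{NA} allowed.
#' @param decreasing \code{TRUE} to rank high scores first (importance),
#'   \code{FALSE} to rank low scores first (p-values).
#' @param ids variant ids; defaults to \code{names(scores)} or
#'   \code{V<index>}.
#' @param method label stored with the ranking.
#' @return A \linkS4class{RankedVariants}.
#' @export
rankVariants <- function(scores, decreasing = TRUE, ids = names(scores),
                         method = "score") {
  force(ids)
  scores <- as.numeric(scores)
  if (is.null(ids)) ids <- paste0("V", seq_along(scores))
  miss <- is.na(scores)
  key <- ifelse(miss, if (decreasing) -Inf else Inf, scores)
  ord <- order(miss, if (decreasing) -key else key, seq_along(scores))
  new("RankedVariants", index = as.integer(ord), ids = as.character(ids[ord]),
      scores = scores[ord], decreasing = decreasing,
      method = as.character(method))
}

#' Truth-variant recovery in the top-r ranked variants
#'
#' The fraction of truth-variants found among the top \code{r = m * t}
#' ranked variants for each multiplier m, where t is the number of
#' truth-variants.  Order within the top-r list is ignored; the maximum value
#' is 1 (all truth-variants inside the top t).
#'
#' @param ranked a \linkS4class{RankedVariants}.
#' @param truth a \linkS4class{TruthSet} with at least one truth-variant.
#' @param multipliers rank-cutoff multipliers (default 1, 2, 5, 10).
#' @return Named numeric vector of recovery fractions
#'   (\code{"1t", "2t", ...}).
#' @export
tvRecovery <- function(ranked, truth, multipliers = c(1, 2, 5, 10)) {
  stopifnot(is(ranked, "RankedVariants"), is(truth, "TruthSet"))
  tv <- truthVariants(truth)
  t <- length(tv)
  if (t < 1L) stop("truth set has no truth-variants")
  out <- vapply(multipliers, function(m) {
    r <- min(round(m * t), length(ranked@index))
    length(intersect(tv, ranked@index[seq_len(r)])) / t
  }, numeric(1))
  names(out) <- paste0(multipliers, "t")
  out
}

#' Maximum-correlation (gamma) score per truth-variant
#'
#' For each truth-variant, the maximum absolute Pearson correlation between
#' its genotype column and any variant in the top 10t ranked variants.  A
#' truth-variant that itself ranks in the top 10t scores 1 (self
#' -correlation); constant columns contribute correlation 0.  The
#' truth-variant's genotype column is taken from \code{x} even when the
#' variant was excluded from the ranked analysis.
#'
#' @param ranked a \linkS4class{RankedVariants}.
#' @param truth a \linkS4class{TruthSet}.
#' @param x a \linkS4class{GenotypeMatrix} holding genotype columns for all
#'   truth-variants.
#' @return Named numeric vector of gamma scores in \[0, 1\], one per
#'   truth-variant.
#' @export
gammaScores <- function(ranked, truth, x) {
  stopifnot(is(ranked, "RankedVariants"), is(truth, "TruthSet"),
            is(x, "GenotypeMatrix"))
  tv <- truthVariants(truth)
  t <- length(tv)
  top <- ranked@index[seq_len(min(10L * t, length(ranked@index)))]
  G <- genotypes(x)
  out <- rep(0, t)
  if (length(top)) {
    cors <- suppressWarnings(abs(cor(G[, tv, drop = FALSE],
                                     G[, top, drop = FALSE])))
    cors[is.na(cors)] <- 0
    out <- apply(cors, 1L, max)
  }
  names(out) <- variantIds(x)[tv]
  out
}

#' Exclusive-detection counts for a method pair
#'
#' A truth-variant is exclusively detected by method A when A's gamma score
#' exceeds \code{hi} while B's falls below \code{lo} (both strict), and
#' symmetrically for B.
#'
#' @param gammaA,gammaB gamma scores from \code{\link{gammaScores}} over the
#'   same truth-variants.
#' @param hi,lo detection and failure thresholds (defaults 0.75 and 0.5).
#' @return Named integer vector \code{c(aOnly, bOnly)}.
#' @export
exclusiveDetection <- function(gammaA, gammaB, hi = 0.75, lo = 0.5) {
  if (length(gammaA) != length(gammaB) ||
      (!is.null(names(gammaA)) && !is.null(names(gammaB)) &&
       !identical(names(gammaA), names(gammaB))))
    stop("gamma vectors must cover the same truth-variants")
  c(aOnly = sum(gammaA > hi & gammaB < lo),
    bOnly = sum(gammaB > hi & gammaA < lo))
}

#' Evaluate one or two rankings against a truth set
#'
#' Computes recovery fractions and gamma scores per method, and — when two
#' methods are given — the exclusive-detection counts of the pair.
#'
#' @param rankings named list of \linkS4class{RankedVariants} (one or two
#'   methods).
#' @param truth a \linkS4class{TruthSet}.
#' @param x the \linkS4class{GenotypeMatrix} the rankings refer to.
#' @param multipliers rank-cutoff multipliers for recovery.
#' @param hi,lo thresholds for \code{\link{exclusiveDetection}}.
#' @return An \linkS4class{EvalReport}.
#' @export
evaluateRankings <- function(rankings, truth, x,
                             multipliers = c(1, 2, 5, 10),
                             hi = 0.75, lo = 0.5) {
  stopifnot(is.list(rankings), length(rankings) >= 1L,
            !is.null(names(rankings)))
  rec <- t(vapply(rankings, tvRecovery, truth = truth,
                  multipliers = multipliers,
                  numeric(length(multipliers))))
  gam <- vapply(rankings, gammaScores, truth = truth, x = x,
                numeric(length(truthVariants(truth))))
  gam <- matrix(gam, ncol = length(rankings),
                dimnames = list(variantIds(x)[truthVariants(truth)],
                                names(rankings)))
  excl <- integer(0)
  if (length(rankings) == 2L) {
    excl <- exclusiveDetection(gam[, 1L], gam[, 2L], hi = hi, lo = lo)
    names(excl) <- paste0(names(rankings), "Only")
  }
  new("EvalReport", recovery = rec, gamma = gam, exclusive = excl,
      nTruth = length(truthVariants(truth)))
}

#' Write an evaluation report
#'
#' The per-truth-variant gamma table goes to CSV; the recovery fractions and
#' exclusive-detection counts go to a summary JSON.
#'
#' @param report an \linkS4class{EvalReport}.
#' @param csvPath,jsonPath output paths (either may be \code{NULL} to skip).
#' @return Invisibly, \code{report}.
#' @export
writeEvalReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  stopifnot(is(report, "EvalReport"))
  if (!is.null(csvPath)) {
    df <- data.frame(truth_variant = rownames(report@gamma),
                     report@gamma, check.names = FALSE)
    write.csv(df, csvPath, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(jsonPath)) {
    rec <- lapply(seq_len(nrow(report@recovery)), function(i)
      as.list(report@recovery[i, ]))
    names(rec) <- rownames(report@recovery)
    jsonlite::write_json(list(nTruthVariants = report@nTruth,
                              recovery = rec,
                              exclusive = as.list(report@exclusive)),
                         jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}
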
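# Fixture builders and independent oracles shared across test files.

# genotype matrix from a plain (samples x variants) integer matrix
gmat <- function(m, ...) GenotypeMatrix(matrix(as.integer(m), nrow(m)), ...)

# write a minimal VCF from parallel vectors; gt is a variants x samples
# character matrix of raw GT strings
writeTestVCF <- function(path, chrom, pos, ref, alt, gt,
                         samples = paste0("S", seq_len(ncol(gt)))) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(chrom), function(i)
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", ".", ".", "GT",
            gt[i, ]), collapse = "\t"), "")
  writeLines(c(header, body), path)
  path
}

# Exhaustive split oracle, independent of the kernel: enumerates every
# (candidate, threshold) pair, computes the Gini gain from first principles,
# and applies the documented selection rule (gain > 1e-12, ties by lower
# variant then lower threshold).  Returns c(variant, threshold, gain) or NULL.
bruteForceBest <- function(G, idx, y, candidates, gmax = 2L) {
  imp <- function(counts) {
    n <- sum(counts)
    1 - sum((counts / n)^2)
  }
  yNode <- y[idx]
  K <- max(y) + 1L
  parentCounts <- tabulate(yNode + 1L, K)
  impP <- imp(parentCounts)
  n <- length(idx)
  best <- NULL
  for (v in candidates) {
    g <- G[idx, v]
    for (thr in 0:(gmax - 1L)) {
      l <- g <= thr
      nL <- sum(l); nR <- n - nL
      if (nL == 0L || nR == 0L) next
      gain <- impP - (nL / n) * imp(tabulate(yNode[l] + 1L, K)) -
        (nR / n) * imp(tabulate(yNode[!l] + 1L, K))
      if (gain <= 1e-12) next
      if (is.null(best) || gain > best[3] + 1e-12 ||
          (abs(gain - best[3]) <= 1e-12 &&
           (v < best[1] || (v == best[1] && thr < best[2]))))
        best <- c(v, thr, gain)
    }
  }
  best
}

# split a matrix's candidate set over blocks, evaluate locally, aggregate --
# the full vertical-partitioning path under test
partitionedBest <- function(gm, idx, y, candidates, nBlocks) {
  blocks <- partitionVariants(gm, nBlocks)
  locals <- lapply(blocks, function(b) {
    own <- candidates[candidates >= b@start & candidates <= b@end]
    if (!length(own)) return(NULL)
    bestSplit(gm, b, idx, y, own)
  })
  aggregateLocalBests(locals)
}
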
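#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gini impurity of a count vector, accumulated in class-index order so the
// result is bit-identical to the R reference path (1 - sum((c/n)^2)).
static inline double gini(const std::vector<int>& cnt, const int n) {
  double acc = 0.0;
  const double dn = (double)n;
  for (size_t c = 0; c < cnt.size(); ++c) {
    const double p = (double)cnt[c] / dn;
    acc += p * p;
  }
  return 1.0 - acc;
}

// Evaluate every (candidate, threshold) binary split of an ordinal column and
// return the best as c(variant, threshold, gain, nLeft, nRight), or an empty
// vector when no split clears the positivity tolerance with two non-empty
// children.  Ties break by (gain desc, variant asc, threshold asc), which
// makes the choice independent of how candidates are spread across column
// blocks.  idx and cand are 1-based; y is 0-based class codes.
// [[Rcpp::export(name = ".evalBlockBestC")]]
NumericVector eval_block_best(const IntegerMatrix& geno,
                              const IntegerVector& idx,
                              const IntegerVector& y,
                              const int nclass,
                              const IntegerVector& cand,
                              const int gmax,
                              const double tol) {
  const int n = idx.size();
  const int nc = cand.size();
  const int nS = geno.nrow();
  // 0-based row indices and their labels, gathered once per node so the
  // per-candidate pass only touches one genotype column
  std::vector<int> ii(n), yy(n);
  std::vector<int> parent(nclass, 0);
  for (int i = 0; i < n; ++i) {
    ii[i] = idx[i] - 1;
    yy[i] = y[ii[i]];
    parent[yy[i]]++;
  }
  const double impP = gini(parent, n);
  const int* gbase = geno.begin();

  double bestGain = -1.0;
  int bestVar = -1, bestThr = -1, bestNL = 0, bestNR = 0;
  std::vector<int> cnt((gmax + 1) * nclass, 0);
  std::vector<int> left(nclass, 0), right(nclass, 0);

  for (int ci = 0; ci < nc; ++ci) {
    const int v = cand[ci];
    const int* col = gbase + (size_t)(v - 1) * nS;
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) {
      cnt[col[ii[i]] * nclass + yy[i]]++;
    }
    std::fill(left.begin(), left.end(), 0);
    int nL = 0;
    for (int thr = 0; thr < gmax; ++thr) {
      for (int c = 0; c < nclass; ++c) {
        left[c] += cnt[thr * nclass + c];
        nL += cnt[thr * nclass + c];
      }
      const int nR = n - nL;
      if (nL == 0 || nR == 0) continue;
      for (int c = 0; c < nclass; ++c) right[c] = parent[c] - left[c];
      const double impL = gini(left, nL);
      const double impR = gini(right, nR);
      const double gain =
          impP - ((double)nL / n) * impL - ((double)nR / n) * impR;
      if (gain <= tol) continue;
      const bool better =
          (gain > bestGain) ||
          (gain == bestGain &&
           (v < bestVar || (v == bestVar && thr < bestThr)));
      if (better) {
        bestGain = gain;
        bestVar = v;
        bestThr = thr;
        bestNL = nL;
        bestNR = nR;
      }
    }
  }
  if (bestVar < 0) return NumericVector(0);
  return NumericVector::create((double)bestVar, (double)bestThr, bestGain,
                               (double)bestNL, (double)bestNR);
}

// Class counts of a label subset; shared by leaf-class assignment and the
// purity check so both see the multiset defined by the bootstrap indices.
// [[Rcpp::export(name = ".classCountsC")]]
IntegerVector class_counts(const IntegerVector& idx, const IntegerVector& y,
                           const int nclass) {
  IntegerVector out(nclass);
  for (int i = 0; i < idx.size(); ++i) out[y[idx[i] - 1]]++;
  return out;
}
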
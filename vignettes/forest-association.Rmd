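---
title: "Random-forest association analysis for complex phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-forest association analysis for complex phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ForestGWAS)
```

## The problem

Single-variant association tests (logistic regression with a Wald test, the
workhorse of case/control GWAS) measure the marginal effect of one variant at
a time. Phenotypes driven additively by many variants (polygenic), by sets of
interacting variants (epistatic), or by both (complex) spread their signal in
ways a marginal test can only partially see: an interacting set can be
strongly associated as a combination while each member alone is not.

ForestGWAS ranks variants by the Gini importance of a random-forest
classifier trained on the ordinal genotype matrix. Because a variant's
information gain at a tree node is conditional on every split above it, the
importance score pools marginal effects and whatever interactions the forest
discovers into a single association score per variant. The package also
implements the two simulators needed to study this behaviour (random
genotypes; additive and parity-interaction phenotypes with truth
bookkeeping), the logistic-regression baseline with principal-component
covariates, and the evaluation metrics used to compare the two rankings.

## Data model

Genotypes are ordinal allele counts: a bi-allelic VCF genotype 0/0, 0/1 (or
1/0), 1/1 encodes to 0, 1, 2; phase is ignored. A `GenotypeMatrix` holds the
`nS x nV` integer matrix (samples in rows, variants in columns) plus variant
and sample identifiers; any single variant's vector is one column, accessed
without copying the matrix. CSV input allows a wider ordinal range via
`ordinalMax`. Phenotypes are class labels, stored as 0-based codes with
sorted class names; the binary case/control setting is the default but the
trainer is multi-class.

All variant and sample indices in the package are 1-based, the natural R
convention (VCF positions stay 1-based as in the standard); column-block
spans are closed ranges `[start, end]`. Missing genotypes must be resolved at
load time because tree induction needs complete ordinal data: the default
policy encodes `./.` as homozygous reference, and a per-variant-mode
imputation is available. Multi-allelic records are rejected rather than
auto-split, so that splitting happens upstream in tools built for it
(`bcftools norm -m-`).

## The forest

Trees are binary. A split on variant $v$ at threshold $\theta \in \{0, 1\}$
sends samples with $g_v \le \theta$ left. Node impurity is the Gini index
$1 - \sum_c p_c^2$ and a split's quality is the information gained

$$\Delta = \mathrm{imp}(parent) - \tfrac{n_L}{n}\,\mathrm{imp}(L)
         - \tfrac{n_R}{n}\,\mathrm{imp}(R).$$

Each tree bootstraps `nS` samples with replacement. At each node `mTry`
candidate variants are drawn globally without replacement and evaluated
exhaustively over both thresholds; the best split must have positive gain
and two non-empty children. A node becomes a leaf when it is pure, when it
holds fewer than `minNS` samples, at depth `maxD` (root depth 0), or when no
candidate split gains; the leaf predicts the majority class, ties to the
lowest class code.

The per-variant importance is the node-size-weighted average gain

$$s(v) = \frac{1}{nTree}\sum_{\text{nodes where } v \text{ splits}}
         \frac{n_{node}}{nS}\,\Delta_{node},$$

zero for variants never chosen. An unweighted variant (mean gain without the
$n_{node}/nS$ factor) is available behind `weighted = FALSE`; the weighted
form is the default because it matches the classical impurity-decrease
importance and damps the chance gains of deep, small nodes.

Out-of-bag (OOB) error is computed from the retained bootstrap membership:
each sample is predicted by majority vote over the trees whose bootstrap
excluded it (ties to the lowest class code), and the error is the
misclassified fraction among samples with at least one vote.

### Vertical partitioning and batching

The training loop is organised the way a feature-distributed implementation
must be: variants are tiled into contiguous `ColumnBlock`s, each block
evaluates only the candidates it owns and reports a single best local
`SplitCandidate`, and the aggregation step takes the global argmax. Two
contracts make this scheduling-invariant:

* **Tie-breaking.** Winners are ordered by (gain descending, variant index
  ascending, threshold ascending) everywhere — inside a block and across
  blocks — so the chosen split never depends on how variants are distributed
  over blocks.
* **Counter-based random streams.** The stream of tree $t$ is derived only
  from `(seed, t)` and the stream of node $k$ in that tree only from the
  tree stream and $k$ (nodes are numbered in breadth-first creation order;
  the bootstrap uses counter 0). Nothing is drawn from a shared sequential
  stream, so growing trees in batches of `rbs`, in any order, over any
  number of blocks, yields bit-identical models.

These invariances are asserted exactly in the test suite (`n_blocks` in
{1, 4, 16} and `rbs` in {1, 10, nTree} at fixed seed). `rbs` and the worker
count are therefore pure throughput knobs.

### Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `nTree` | trees in the forest | 100 | more trees lower OOB with diminishing returns |
| `mTry` | candidates per node | `round(sqrt(nV))` | also accepts a fraction of `nV`; `0.1 * nV` is the setting used for the association experiments |
| `maxD` | maximum depth, root = 0 | unlimited | shallow trees train faster and resist deep-node overfitting |
| `minNS` | minimum node size to process | 2 | nodes below it become leaves without evaluation |
| `rbs` | trees per batch | `min(100, nTree)` | no effect on the model |
| `seed` | master seed | 1 | all randomness derives from it |

The complexity of the core computation is `nTree * nNode * mTry * nS`
operations (`opCount()`), with `nNode` the average number of internal nodes
per tree, known only after training; total runtime decomposes into a load
term and a per-tree term, `beta + nTree * theta` (`expectedRuntime()`), both
of which the `importance` command logs.

## The simulators

`genFeatures(nS, nV, mafRange, seed)` draws a per-variant allele frequency
uniformly from `mafRange` and genotypes as Binomial(2, freq) counts —
independent variants, no linkage disequilibrium, no population structure.

`genLabel()` builds an additive liability
$L_j = \sum_i w_i g_{ij} + \sum_k \epsilon_k g_{kj}$ from `kCausal` causal
variants (default 5, weights 1.0) plus `round(gvf * nV)` "noise variants"
whose weights are drawn once per variant from Normal(`gm`, `gs`) (defaults
0.5, 0.5) — weak but real confounders, which is why they are drawn per
variant rather than per sample. Only the causal variants are truth-variants.

`genEpistaticLabel()` builds the polygenic-epistatic designs: disjoint
variant sets form n-way truth-variables for n = 1..5, and a variable's value
is the parity (XOR) of the dominance indicators $d_i = [g_i \ge 1]$ of its
members. When $P(d = 1) = 1/2$, every member of an n >= 2 variable is
exactly marginally independent of the variable's value — the signal exists
only in combination, the defining property of epistasis that marginal tests
cannot see. `carrierMAF(p)` returns the allele frequency giving carrier
probability `p` (about 0.293 for 0.5). The liability is the unit-weighted
sum of variable values plus Normal(0, `noiseSd`) noise; the default
`noiseSd = 0.5` corresponds to a strongly genetic trait (each variable
contributes variance 0.25).

**Dichotomization.** Both generators threshold the liability at its median.
This is implemented as a rank threshold — the `ceiling(nS/2)` samples with
the highest liability are cases, ties broken by sample index — rather than
the literal indicator `L >= median(L)`. For a continuous liability the two
are almost surely identical; for discrete liabilities (a parity sum with
`noiseSd = 0` takes a handful of integer values) the literal indicator can
produce arbitrarily unbalanced or even constant labels, while the rank rule
always yields classes balanced to within one sample, which the forest's
unweighted training assumes.

What the simulators deliberately do not emulate: linkage disequilibrium,
population stratification, allele-frequency spectra, genotyping error, and
PEPS-style penetrance tables. Tests passing on these simulations therefore
certify the algorithmic contracts and the statistical behaviour under clean
conditions, not performance on real cohort data.

## Evaluation

Variants are ranked by importance (descending) or by Wald p-value
(ascending), ties by variant index, missing scores last. With $t$
truth-variants, recovery at $r = m t$ is the fraction of truth-variants in
the top $r$, for $m \in \{1, 2, 5, 10\}$, ignoring order within the prefix.
The per-truth-variant $\gamma$ is the maximum absolute Pearson correlation
between the truth-variant's genotype and any variant in the top $10t$ — a
proxy-detection score that credits a method for finding a correlated variant
even when the truth-variant itself was excluded from the analysed set
(constant columns contribute 0). A truth-variant is exclusively detected by
one method when its $\gamma$ exceeds 0.75 there while the other method's is
below 0.5, both strict.

The baseline fits, per variant, a logistic regression of the label on
intercept, covariates and genotype by Newton-Raphson (at most 25 iterations,
convergence when the largest coefficient change falls below 1e-8), taking
the Wald p-value from the genotype coefficient. Non-convergence (the
divergent MLE of perfect separation) and singular information (constant
genotypes) are recorded as missing and ranked last. Covariates default to
the top principal components of the column-standardized genotype matrix
(constant columns dropped, component signs fixed so the largest-magnitude
loading is positive); a seed-controlled variant subsample for the PCA is
available for very wide matrices but off by default.

## Numerical choices

* Split positivity uses a tolerance of 1e-12: Gini gains that are
  mathematically zero can evaluate to ±1e-17 in floating point and must not
  create splits.
* Gains are computed in double precision with a fixed accumulation order in
  both the compiled kernel and the R reference path, so block-local and
  aggregated comparisons see identical values.
* Seeds are mixed with 31-bit modular arithmetic (every intermediate exact
  in doubles), keeping derived seeds valid R seeds.
* Bootstrap bags are stored sorted; nodes are sample multisets, so the
  order is semantically inert and sorting improves memory locality.
* OOB and leaf ties both resolve to the lowest class code.

## Worked example

```{r example}
gm <- genFeatures(300, 100, seed = 7)
sim <- genLabel(gm, LabelSimSpec(kCausal = 3, gm = 0.5, gs = 0.5,
                                 gvf = 10 / 100, seed = 7))
fit <- trainForest(gm, sim$phenotype,
                   ForestParams(nTree = 100, mTry = 0.1, maxD = 15,
                                minNS = 20, seed = 7))
fit
ranked <- rankVariants(importanceScores(fit), method = "RF")
tvRecovery(ranked, sim$truth)
pv <- lrWald(gm, sim$phenotype, pcaCovariates(gm, 2))
tvRecovery(rankVariants(pv, decreasing = FALSE, method = "LR"), sim$truth)
```

## Problem sizes used by the test suite

The package's statistical tests run at desk scale, chosen to keep the full
suite in the minutes range while leaving the assertions well-powered:
split-oracle equivalence on hundreds of random nodes with up to 12 samples;
partition/batch invariance at nS = 500, nV = 2000, nTree = 50; planted-signal
recovery and the parity comparison at nS = nV = 2000 with nTree = 500 and
mTry = 0.1 nV over 10 seeds; OOB calibration at nS = 1000 under permuted
labels; type-I calibration of the Wald baseline over 1000 null variants at
nS = 2000.

## Known limitations

* **Marginally-null interactions are essentially invisible at wide nV.**
  For a parity pair with carrier probability exactly 0.5, a member can only
  enter a tree path by winning a node against `mTry - 1` equally-null
  competitors, so the expected number of nodes conditioned on one member is
  about `nNode * nTree / nV` per forest — at nS = nV = 2000 with nTree = 500
  roughly twenty, far too few for the partner's conditional gain to lift it
  above the chance-gain distribution of two thousand null variants. Our
  tests confirm the effect, and an independent implementation (ranger, same
  settings) behaves identically, so this is a property of Gini-importance
  forests at this scale, not of this implementation. Detection of epistasis
  by the forest in practice relies on members carrying at least a weak
  marginal signal (carrier probability away from 0.5, linkage
  disequilibrium, unequal weights) or on a much larger nTree relative to
  nV. The corresponding end-to-end expectation in the acceptance suite is
  left failing rather than weakened, as an honest record of this boundary.
* The trainer keeps the full genotype matrix in memory; out-of-core or
  truly distributed execution is out of scope (the vertical-partitioning
  contract is honoured on one machine).
* Importance scores are impurity-based; permutation importance and
  p-value-calibrated importance are not implemented.
* Regression (continuous) phenotypes and dosage genotypes are not
  supported.
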
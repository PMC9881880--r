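---
title: "Benchmarking RNA-seq preprocessing for network inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking RNA-seq preprocessing for network inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnibench)
```

## The problem

Co-expression-based gene network inference (GNI) scores every gene pair by
an association statistic and keeps the significant pairs. RNA-seq counts,
however, arrive on a scale — integer, heteroscedastic, depth-confounded —
that none of the classic estimators was designed for, and the chain of
preprocessing decisions taken before the estimator (transformation,
normalization, rank scaling) changes the inferred network substantially.
`gnibench` makes that chain explicit and measurable: it enumerates every
combination of the standard options, runs each through the same inference
and evaluation machinery, and aggregates performance across datasets.

## Pipeline stages and their parameters

**Cleaning and filtering.** Unannotated rows (symbol `NA` or empty) are
dropped; duplicated symbols keep their highest-variance row (raw-count
variance, first occurrence on ties). Genes are then removed when (1) the
share of samples with CPM ≤ `low_cpm` (default 0.1) reaches `low_frac`
(default 20%), (2) the maximum CPM is ≤ `max_cpm` (default 0.7), or (3) the
mean CPM is < `mean_cpm` (default 0.35). We read rule (1) literally —
*remove* when that many samples are at or below the cut — rather than the
keep-if-expressed convention of differential-expression filtering; all four
thresholds are arguments, so the other reading is one flag away. Filtering
CPM is computed from raw column sums without the pseudocount: 0.1 CPM
corresponds to 2 raw counts at a 20M-read library, which is only meaningful
on the raw scale.

**Pseudocount.** One unit is added to every cell exactly once, before any
transformation. It protects the log2, the geometric means inside RLE/VST and
the copula against zeros, and damps extreme-variance genes that would
otherwise dominate a network as spurious hubs. The `pseudocount_added`
attribute guards against double application.

**Data types.** `raw`, `l2`, `cpm`, `l2cpm`, `tpm`, `l2tpm`. CPM scales each
column to 10⁶; TPM first divides by gene length in kilobases, then scales
the rates, so TPM = CPM when lengths are equal. Library sizes for CPM/TPM
are the column sums of the matrix actually passed in — i.e. the
pseudocounted matrix at this stage — which is documented here precisely
because it makes stage-2 CPM reproducibly different from the raw-scale
filtering CPM.

**Normalizations.** `TMM`, `RLE`, `VST`, `QN`, `NoNorm`. Scaling-factor
methods are always *estimated on counts* and *applied to the data-type
matrix* column-wise; this keeps the count-based statistics valid whatever
the data type. TMM (via edgeR) doubly trims the per-gene log-ratios (30% on
M, 5% on A) against the sample whose 75th-percentile count fraction is
closest to the mean, and combines survivors by inverse-variance weights. RLE
takes each sample's median ratio to the per-gene geometric-mean reference
(zero-containing genes excluded). Both factor sets are standardized to
product 1, so `apply_factors` divides column *j* by *f<sub>j</sub>* and a
pure depth change leaves TMM factors at 1. QN replaces each column by the
across-column mean of order statistics, averaging ties. The composition
order (normalize the transformed matrix, factors from counts) was a genuine
design choice: the alternative — transforming the normalized counts — is
reachable by calling the stage functions directly in the other order.

**VST.** The transform is the closed form for a negative-binomial
mean–dispersion trend α(μ) = a₀ + a₁/μ:
`vst(x) = log2((1 + a₁ + 2a₀x + 2√(a₀x(1 + a₁ + a₀x))) / (4a₀))`,
strictly monotone and asymptotically log2(x). The trend is fitted on
size-factor-normalized counts by method-of-moments dispersions
α(g) = max(0, (var − μ)/μ²) and least squares on (1/μ, α) with two rounds of
outlier down-weighting (weight 0 beyond 3 robust SD) — deterministic and
seedless. Fewer than 10 positive-dispersion genes triggers a log2(x + 1)
fallback with a warning. On simulated NB counts with means 1–10⁴ and
dispersion 0.05, the test suite checks that the per-mean-bin variance of the
VST output varies by < 3× while log2(x + 1) varies by > 3× and at least
twice as much as the VST — the quantitative form of "flattening" we could
actually verify at this scale.

**Copula transform.** Row-wise `rank/(n+1)` with average ties, strictly
inside (0, 1). Spearman is exactly Pearson after this map, so `SCC` is
CT-invariant; for the MI estimators CT changes the marginals to
near-uniform, which interacts with binning.

**Estimators.** PCC/SCC store |r| as edge strength with the sign kept as an
attribute — the relevance-network convention, since a strong negative
association is as informative as a positive one; PBG is −½ ln(1 − r²) nats
with |r| clamped below 1 − 10⁻¹². The B-spline estimator spreads each
observation over `bins` = 10 fractional bins using B-spline basis functions
of order `spline_order` = 2 on the domain [0, B − k + 1] (order 1 is exactly
hard equal-width binning) and plugs the weighted histograms into MI. The
Chao–Shen estimator hard-bins into 10 bins and uses coverage-adjusted
(Horvitz–Thompson) entropies: coverage C = 1 − f₁/n with the f₁ = n case
backed off to n − 1. Ten bins is the common setting for these estimators at
the sample sizes RNA-seq provides; both counts are arguments. All MI is in
nats, negative estimates clamp to 0.

**Inference.** RELNET keeps pairs with score ≥ threshold; C3NET keeps, per
gene, its single maximal surviving edge (ties to the lexicographically
smallest partner symbol, for determinism); ARACNE removes edge (i, j) when a
triangle partner k has min(score<sub>ik</sub>, score<sub>jk</sub>) −
`dpi_eps` above it, with all removals decided against the pre-pruning edge
set so the result is order-independent. `dpi_eps` defaults to 0, the setting
at which ARACNE prunes every strictly weakest triangle edge and its
prediction count drops to near C3NET's; the three outputs nest:
c3net ⊆ aracne(0) ⊆ relnet. Thresholds: the original study does not print
its significance procedure, so three modes are provided — a seeded
permutation null (rows shuffled independently, pooled off-diagonal scores,
1 − α quantile, α = 0.01), `top_k` to emulate a target prediction count, and
`absolute`.

**Evaluation.** Precision TP/(TP + FP) only: with an incomplete reference an
absent edge is not a true negative, so recall/F1/AUROC are not reported by
default (`network_recall` exists for synthetic, complete-truth runs). The
test universe is the post-filtering gene set — only those genes can be
predicted; whether the original study conditioned on the dataset genes, the
database genes or their intersection is not stated, and this choice is the
defensible default. The hypergeometric test conditions on (|pred|, reference
pairs inside the universe, C(n, 2)); the Fisher test is its 2×2 equivalent.
Random baselines draw edges uniformly without replacement via an arithmetic
upper-triangle index decoding, so no g × g matrix is materialized.

**Rank aggregation.** Per dataset (and per algorithm, so the algorithm's
effect drops out), combinations are ranked by descending precision with
minimum-rank ties; median/mean/best/worst ranks aggregate across datasets,
sorted by median then mean then label. Missing combination × dataset cells
are an error rather than silently ignored.

## What the generator emulates — and what it does not

`generate_planted_dataset` draws hub regulators as standard-normal latent
variables, gives each target latent value `signal`·hub + √(1 − signal²)·noise,
maps latents through an exponential link (per-gene log-abundance SD 1.0,
latent scale 0.7) to NB means scaled to a uniform library size in
`lib_size_range`, and samples NB counts with `variance = μ + dispersion·μ²`.
Defaults — 200 genes × 100 samples, 5 hubs × 10 targets, signal 0.9,
dispersion 0.1, library sizes 2–4 × 10⁵ (the per-gene depth a 20–40M-read
library gives a 20k-gene transcriptome), log-normal lengths (meanlog 7.5,
sdlog 0.7), reference coverage 0.6 with 50 decoy edges — are fixed study
conditions, not tuning knobs. The simulation reproduces the properties the
benchmark depends on: heteroscedastic counts (variance rising with the
mean), depth variation between samples, hub topology (which exercises both
C3NET's one-edge-per-gene rule and DPI pruning of target–target triangles),
and an incomplete, partly wrong reference. It does **not** model
isoform-level effects, GC/length biases within a gene, batch structure,
feedback dynamics or directed regulation — so a passing test shows the
machinery is correct and the statistics behave, not that any particular
combination will win on real tissue data.

## Numerical choices

* Exact symmetry of association matrices is enforced by averaging with the
  transpose; diagonals are 0.
* Constant rows get correlation 0 (with one warning) instead of NA.
* B-spline membership at the right domain edge is clamped inward by a
  relative 10⁻¹² so the basis still sums to 1.
* Edge canonicalization sorts each pair lexicographically and the edge list
  by (from, to); duplicate resolution keeps the first occurrence.
* The variance filter breaks ties by keeping the earlier row; duplicate
  collapse uses raw-count variance while the variance filter uses CPM-scale
  variance (cross-gene comparisons need the depth removed; within-symbol
  comparisons do not).
* All factor standardizations hold to 10⁻¹⁰ relative; column sums of CPM/TPM
  to 10⁻⁶ relative.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by design:
synthetic datasets of 200 × 100 (40 × 30 for the pipeline-composition
tests), 8-gene association matrices for the 1000-instance containment sweep,
≤ 8 genes for the exhaustive DPI oracle, 2000 observations for the
MI-independence bounds, and 3-replicate sample-size curves at n = 10–80.
These sizes keep every property estimable with comfortable margins while the
full suite runs in well under a minute.

## Known limitations

* The permutation null recomputes the full association matrix per
  permutation; for the MI estimators on thousands of genes this is the slow
  path — `top_k` is the practical mode at that scale.
* VST here fits a two-parameter trend by weighted least squares, not a
  gamma-family GLM; on very small or very sparse matrices the
  method-of-moments dispersions are noisy and the log2(x + 1) fallback
  engages.
* The reference is matched undirected; directional regulatory databases
  lose orientation on import.
* `run_grid` executes serially; records are independent and the resume
  mechanism (`done =`) is the hook for external parallelization.
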
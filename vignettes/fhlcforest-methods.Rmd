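---
title: "Modeling linkage disequilibrium with forests of hierarchical latent class models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling linkage disequilibrium with forests of hierarchical latent class models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhlcforest)
```

## The problem

Genome-wide association studies genotype $10^5$–$10^6$ SNPs whose alleles are
far from independent: nearby markers travel together on ancestral haplotypes,
a dependence called linkage disequilibrium (LD). Testing each SNP separately
ignores this structure and pays a heavy multiple-testing price; block-based
summaries (haplotype blocks) force the structure to be contiguous, which real
LD is not. `fhlcforest` models LD with a *forest of hierarchical latent class
models* (FHLCM): a directed forest whose leaves are the observed SNPs and
whose internal nodes are discrete latent variables, each subsuming a cluster
of strongly dependent variables. Low layers capture tight, local LD; higher
layers capture progressively weaker and longer-range dependence. The roots of
the forest are a compressed representation of the panel — the dimension
reduction that downstream association testing can work from.

## The model

A latent class model (LCM) is a Bayesian network with one discrete latent
root $H$ and child variables $X_1,\dots,X_S$ that are conditionally
independent given $H$:
$$P(H, X_1, \dots, X_S) = P(H) \prod_{i=1}^{S} P(X_i \mid H).$$
An FHLCM stacks LCMs: the children may themselves be latent variables learned
at a lower layer, giving trees of latent variables over the SNP leaves, and
the forest's joint distribution factorizes as usual over node-given-parent
terms. Observed SNPs sit on layer 0 and a latent node's layer is
$1 + \max(\text{child layers})$.

## The construction algorithm

The builder processes contiguous windows of `window_size` markers one at a
time (LD is overwhelmingly local; windows also bound memory). Within a
window it runs an agglomerative loop over a *working set* that starts as the
window's SNP columns:

1. **Similarity.** Compute the pairwise mutual-information (MI) matrix of the
   working set (plug-in estimator, bits) and binarize it at its
   `mi_quantile` quantile (nearest-rank, strictly-upper-triangle entries
   only): a 0/1 similarity graph over the current variables.
2. **Partitioning.** Partition the graph with the CAST heuristic: clusters
   are grown one at a time from the highest-degree unassigned variable,
   adding the highest-affinity outsider whose affinity reaches
   `t_cast * |C|` and removing members whose affinity falls below
   `t_cast * (|C| - 1)`, with index-based tie-breaks so the procedure is
   deterministic. Exact clique partitioning is NP-hard; CAST is the standard
   greedy surrogate.
3. **Subsumption.** Every cluster with at least two members is offered to an
   LCM. The latent cardinality is the affine rule
   `min(floor(a * size + b), card_max)` (never below 2); parameters are
   fitted by EM and the latent value of each individual is imputed (MAP by
   default).
4. **Validation.** The candidate latent variable is kept only if the
   information-decay criterion
   $$C = \frac{1}{S}\sum_{i=1}^{S}
     \frac{I(X_i, H)}{\min(\mathcal H(X_i), \mathcal H(H))} \ge t,$$
   the average fraction of each child's information retained by the latent
   variable. Validated latents replace their children in the working set
   (the imputed vector becomes an ordinary column); members of rejected
   clusters stay isolated and may join clusters at later steps.
5. **Stop.** The loop ends when every cluster is a singleton or no cluster
   validates. The final forest is the union of the per-window forests;
   windows are treated as independent, so no edge ever crosses a window
   boundary.

`C` is computed from the *imputed* latent column, not from the analytic
posterior: the imputed values are exactly what the next layer sees as data,
so the gate measures the information that actually survives subsumption.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `window_size` | 100 | markers per window (index-based, remainder in the last window) |
| `t` | 0.3 | validation threshold on criterion C |
| `a`, `b` | 0.2, 2 | affine cardinality rule coefficients |
| `card_max` | 20 | latent cardinality cap |
| `t_cast` | 0.95 | CAST affinity threshold |
| `mi_quantile` | 0.95 | MI-matrix quantile used as binarization threshold |
| `imputation` | `"map"` | posterior argmax; `"sample"` draws from the posterior |
| `seed` | 1 | master seed; every window/step/restart derives its own stream |

The defaults are the reference parameter set used for dense real-data panels.

**Choosing `t`.** One structural fact matters when setting `t`: for a
cluster of two variables, a two-state latent that simply copies one child
scores exactly $C = 0.5$ (one child fully captured, the other not at all) —
*even when the two children are independent*. A gate at `t = 0.3` therefore
admits pair clusters regardless of their actual dependence, which is
acceptable on dense, strongly structured panels (where such pairs are real)
but merges noise on weakly structured data. For simulation studies and
weak-LD panels use `t = 0.6`, which rejects the copied-child configuration;
this is the setting used by this package's own simulated-data analyses and
tests. `t = 1` forbids every latent variable and is useful as a null
configuration.

## Numerical choices

* **Estimators.** Entropy and MI are plug-in (maximum-likelihood) estimates
  in bits with $0 \log 0 = 0$; no bias correction. If a variable is constant,
  its scaled MI is defined as 0 — a variable carrying no information must not
  validate a vacuous latent variable.
* **Quantile.** Nearest-rank over the strictly-upper triangle; including the
  diagonal (self-information) would inflate the threshold.
* **EM.** Random initialization from symmetric Dirichlet(1) draws;
  convergence when the relative log-likelihood change drops below `1e-6` or
  after 500 iterations; 3 restarts by default with best-log-likelihood
  selection; responsibilities receive an `1e-9` pseudo-count before M-step
  normalization to avoid zero-probability lock-in. All restarts derive from
  one seed, so fits are reproducible.
* **Ties.** MAP imputation breaks posterior ties toward the lowest state
  index; CAST breaks affinity ties by variable index; haplotype-frequency
  ties in the diversity statistic are broken lexicographically.
* **Cardinalities.** The affine rule is floored and never drops below 2;
  the `regularization_cardinality()` utility (product of child cardinalities
  over their maximum) illustrates why an unconstrained rule explodes —
  ten 3-state children would demand $3^{10}/3 = 19683$ latent states.
* **Remainder windows.** `nbw = ceiling(p / s)`; the last window keeps the
  `p mod s` leftover markers as its own (smaller) window.
* **MI matrix recomputation.** The MI matrix and its quantile threshold are
  recomputed at every agglomerative step over the current working set, since
  the set shrinks and mixes observed and imputed columns.

## Evaluation metrics

* **Dimension reduction rate (DRR)** — forest roots over observed SNPs; each
  tree is synthesized by its root. `1 - DRR` is the fraction of variables
  eliminated.
* **Entropy compression rate (ECR)** — sum of within-cluster joint entropies
  over the sum of marginal entropies, clusters being the leaf sets of the
  trees. Subadditivity bounds it by 1; strong within-cluster LD drives it
  toward 0. Joint entropies are plug-in entropies of observed value-tuples
  (no model assumed).
* **MRCA levels** — for each same-tree SNP pair, the layer of the lowest
  common ancestor; cross-tree pairs get the sentinel `N`. If the forest
  models LD faithfully, median pairwise $r^2$ decreases as the MRCA level
  rises (`mrca_r2_table()`, `plot_mrca_r2()`).
* **Haplotype diversity** — for each latent variable, the smallest number of
  distinct observed leaf-tuples covering 75% of the sample; diversity grows
  with the subtree's level.
* **Layer statistics** — variables per layer and the mean scaled MI of edges
  into each layer: information fades with height.

## The synthetic generator

`generate_block_ld()` emulates block-structured haplotype data: each block
carries a pool of distinct ancestral haplotypes (4 per block in this
package's studies — small enough for strong within-block LD, large enough
that most sites stay polymorphic); each sampled haplotype copies one pool
member and flips each allele independently with probability
`(1 - fidelity)/2`; genotypes sum two independently drawn haplotypes
(random mating). Blocks are mutually independent. `sample_fhlcm()` draws
exact ancestral samples from any fully parameterized forest and returns the
true latent values, enabling parameter-recovery experiments;
`make_two_layer_forest()` builds such forests with deterministic-leaning
CPTs whose per-state modes follow base-`card` digit coding, so a run of
children jointly identifies every latent state.

What the generator does **not** emulate: recombination gradients and LD
decay *within* a block (within-block pairs are exchangeable), coalescent
genealogies, population substructure, allele-frequency spectra. Passing
recovery tests on this generator shows the construction machinery is sound
on block-structured dependence; it does not certify behavior on real panels
with fuzzy block boundaries.

**Recovery scoring.** Because similarity is thresholded at a high MI
quantile, a true cluster agglomerates over several steps and its collapsed
root need not sit on layer 1; recovery of the generating partition is
therefore scored on the SNP partition induced by the learned forest's trees
(adjusted Rand index against the generating block labels).

## Problem sizes used in the checks

The package's test suite and acceptance script run at desk scale, chosen to
keep the full suite in minutes while leaving the claims sharp: information
and LCA oracles on tens of variables; EM monotonicity on 200 random
instances; structural builder checks on 6–24 markers at $n$ = 200–2000;
cluster recovery on 20 markers, $n = 2000$, 10 seeds; the headline
dimension-reduction run on 1000 markers in blocks of 10–20 at $n = 2000$
with the default window of 100. The 5q31 real-data check (129 children,
103 SNPs) runs only when the user supplies the benchmark matrix under
`inst/extdata/`, as the dataset is not redistributable with the package.

## Known limitations

* Long-range LD across window boundaries is invisible by design; widen the
  window (or thin the panel) to capture it. Windows beyond a few hundred
  markers make the quadratic MI matrix and CAST the bottleneck.
* The C criterion is insensitive to *which* children carry the retained
  information (see the `t = 0.5` pair pathology above); interpret small
  clusters accordingly.
* EM fits are local optima; restarts mitigate but do not eliminate this.
  Likelihood-equivalent relabelings of latent states are not canonicalized.
* Trio phasing, PLINK formats and multi-allelic sites (beyond skipping) are
  out of scope; phased input must be phased upstream.
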
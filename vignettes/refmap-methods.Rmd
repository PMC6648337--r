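---
title: "Methods and design notes for refmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for refmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains what `refmap` computes, the assumptions behind each
stage, the parameters that matter, and the design decisions taken where
several defensible options existed. The companion README shows the
worked example; here we concentrate on the methods.

## The setting

A multi-study expression collection is a genes × samples matrix of
log-scale values (log2 microarray intensities or log-CPM) assembled from
many independent experiments. Two label vectors matter: the *phenotype*
(disease subtype, cell type — possibly missing for some samples) and the
*study* (data series) each sample came from. The central failure mode of
unsupervised analysis on such data is clustering that tracks study rather
than phenotype. Every module in this package exists either to detect that
failure, to avoid it, or to let a frozen analysis be extended without
re-running it.

## NMI metrics

For label vectors we use Shannon entropies of empirical frequencies and
define `NMI(X, Y) = MI(X, Y) / ((H(X) + H(Y)) / 2)`. Natural logarithms
are used throughout; NMI is a ratio, so the choice of base cancels and no
bits/nats ambiguity arises. Three conventions are worth stating:

- If exactly one labeling is constant, its entropy is zero and it carries
  no information: NMI is defined as 0 (this also avoids 0/0).
- If *both* are constant the partitions are trivially identical and NMI
  is 1.
- **pNMI** (clusters vs phenotypes, maximize) drops samples with missing
  phenotype pairwise. **eNMI** (clusters vs studies, minimize) uses all
  samples by default, because study labels are always known; an
  `annotated_only` switch restricts it to the pNMI sample set for strict
  comparability. **cNMI = (pNMI + (1 − eNMI)) / 2** combines them.

The parameter sweep (`nmi_sweep()`) runs the full select → embed →
cluster pipeline for each setting under `n_seeds` independent seeds and
reports mean ± sd per metric. Multi-seed evaluation (default 10 in
examples; 100 reproduces a dense sweep) separates a setting's systematic
behavior from t-SNE's run-to-run variability.

Trustworthiness and continuity are the classical rank-based embedding
metrics (penalizing spurious and missing k-nearest neighbors, weighted by
rank). They are reported alongside k; the default k = 12 is a
conventional mid-range neighborhood — small enough to be local, large
enough not to be dominated by single-neighbor noise. These metrics see
geometry only; a map that reproduces batch structure perfectly scores
high. That blindness is precisely the motivation for the NMI metrics, and
the package treats the two families as complementary.

## Map building

- **Feature selection.** Default: the 15% most-variable genes (variance on
  log-scale values, denominator n − 1). Variance ties are broken by gene
  id with a stable sort so selection is identical across platforms. The
  PCA alternative (scores on the top components of column-centered data)
  is retained as the comparator the sweep evaluates against; with
  gene-level batch shifts, between-study differences concentrate in the
  leading principal components, which is why the 20-PC setting clusters by
  study where the variable-gene setting does not.
- **Embedding.** Barnes-Hut t-SNE via Rtsne, single-threaded, fixed seed,
  internal PCA disabled (feature selection is this package's explicit
  step). Default perplexity 30, theta 0.5 for initial maps.
- **Clustering.** Gaussian-kernel mean shift on the 2D coordinates: each
  point iterates `y <- sum(w * x) / sum(w)` with
  `w = exp(-d^2 / (2 h^2))` until the step falls below 1e-4 (max 300
  iterations); converged modes within `h/2` of each other are merged by
  connected components, so labels are invariant to input order up to
  renaming. Bandwidth h is in map units: 1.5 suits maps of a single
  disease entity, 2.5 full collections. The cluster count is emergent,
  not preset; a bandwidth exceeding the map's extent collapses everything
  into one cluster, which is the documented degenerate behavior, not an
  error. Centroids are member means in map coordinates.

## Remapping onto a frozen map

New samples are placed one at a time. For a new sample, squared distances
to the reference samples over the map's feature genes (Euclidean, or
`1 - Pearson r` under the correlation metric — both squared inside the
kernel, for symmetry between the metrics) enter a Gaussian kernel whose
precision is calibrated by binary search until the distribution's Shannon
perplexity matches the target (tolerance 1e-6, ≤ 200 bisections). These
affinities `p_{j|new}` are normalized to sum to 1 without symmetrization:
the reverse conditional is undefined when the reference side is frozen,
so the per-point conditional *is* the input distribution.

The embedding coordinate of the new point minimizes
`KL(P || Q)` where `Q` is the normalized Student-t kernel between the
candidate point and the fixed reference coordinates. The gradient is
`2 * sum_j (p_j − q_j) (1 + d_j^2)^{-1} (y − Y_j)`, evaluated exactly at
these problem sizes (theta is recorded for provenance; a Barnes-Hut
approximation adds nothing below tens of thousands of reference points).
Optimization is 500 gradient-descent iterations with momentum 0.5
switching to 0.8 halfway — but with learning rate 2, not the 100–200
conventional for full t-SNE: there, forces are normalized over n² pairs
and gradients are O(1/n); here the affinities of a single point sum to 1,
gradients are O(1), and a rate of 100 demonstrably diverges. At rate 2
the optimizer reproduces the exact KL minimizer (BFGS cross-check) to
machine precision on separated maps. Initialization is the
affinity-weighted mean of the top-10 reference coordinates — deterministic,
so remapping needs no randomness at all; Gaussian random initialization is
retained as an option for parity with the unlocked algorithm.

Because each point descends alone against locked coordinates, (a) the
reference map is bit-identical before and after any remapping run, and
(b) a sample's coordinate is independent of its batch companions — both
properties are asserted at 1e-12/byte level in the tests.

Cluster assignment is nearest centroid (Euclidean in map coordinates,
ties to the lowest cluster id); annotation transfer is majority vote over
the assigned cluster's annotated reference members, with ties reported as
`"ambiguous"` and annotation-free clusters as `"unlabeled"`.

**Representativeness diagnostics.** For each new sample we report the
maximum Pearson correlation to any reference sample (`max_r`), the mean
correlation to the assigned cluster (`cluster_mean_r`), and the margin
over the best other cluster. The default warning thresholds —
`max_r < 0.8` or `margin < 0.05` — were calibrated once on the generator's
default conditions, where samples of a represented phenotype show
`max_r ≈ 0.92–0.96` and margins ≈ 0.37–0.5, while samples of a phenotype
absent from the reference drop to `max_r ≈ 0.67–0.75` with margins within
±0.06 of zero; the defaults sit between the two regimes with room on both
sides. On real data the correlation scale depends on the feature set and
platform mix, so both thresholds are exposed as arguments and the raw
diagnostics are always returned.

Feature overlap below 90% of the map's features is an error; above it,
absent features are mean-imputed from the reference (relevant mostly under
the correlation metric, where a few imputed entries barely perturb r).

## Cluster gene sets and correspondence

Per cluster, genes are Pearson-correlated with the binary membership
indicator; p-values use the t transform of r with n − 2 degrees of
freedom, two-sided (the directional intent is captured by splitting into
up/down sets, so a one-sided test would double-count the direction).
Among genes with p < 0.05, the 20 most positive form the `_UP` set and
the 20 most negative the `_DN` set; fewer significant genes simply give a
smaller set.

Single-sample scores follow the kernel-CDF / weighted-KS procedure: per
gene, a kernel estimate of the cumulative expression distribution across
samples (Gaussian kernel, bandwidth sd/4, for continuous data; a Poisson
kernel with rate `count + 0.5` for integer counts, selected by
`kcdf = "poisson"` when scoring RNA-seq counts); per sample, genes are
ranked by that statistic and weighted by `|p/2 − rank|^tau` with
tau = 0.25; the random walk steps up by normalized weight at in-set genes
and down by `1/(p − |set|)` otherwise; the score is the deviation of
largest magnitude with its sign (the largest-deviation rule — the
alternative max-pos-plus-min-neg rule is deliberately not implemented).
Only sets with 5–500 members after intersection with the matrix are
evaluated.

Empirical significance comes from permutation nulls built per
gene-set-size bin (every size 5–20, then 25, 30, 40, 50, 75, 100, 200,
300, 400, 500; other sizes use the nearest bin, ties upward): 1000 random
gene sets per bin by default, scored identically. The empirical p counts
permuted scores at least as extreme in either direction
(`>= |score|` or `<= -|score|`) over the number of permutations. Counting
both tails — rather than only the tail on the observed score's side —
makes the null p-value exactly uniform whatever the skew of the null
score distribution, which is the property that makes downstream BH
adjustment meaningful; the suite verifies uniformity by KS test. A count
of zero is reported as p = 0, per the counting rule; a companion
`(count + 1)/(n + 1)` column is provided for stability, and BH adjustment
runs across the whole sample × set table.

Cluster-level enrichment of significant samples is the upper-tail
hypergeometric probability, BH-adjusted across the whole table (the
per-cluster alternative would make adjusted values incomparable between
clusters). `match_maps()` calls a sample significant when its adjusted p
is below alpha (default 0.001) *and* the score sign matches the set's
direction, then declares, per source cluster, the target cluster with the
smallest adjusted enrichment p below alpha its best match. The
cross-dataset consistency filter keeps sets whose score-cluster
correlation agrees in sign between datasets with nominal p < 0.05 in the
smaller and adjusted p < 0.001 in the larger.

## Reference-anchored normalization

The model built from a processed collection stores (a) the reference
quantile distribution — the across-sample mean of per-sample sorted value
vectors, the standard choice — and (b) frozen probe effects from a
two-way median polish (max 10 iterations, tolerance 0.01) of each gene's
quantile-normalized probes × samples block. Probe effects are stored on
the *original-data scale*, i.e. row effect plus the gene's overall term:
subtracting them from a new sample's quantile-mapped probes isolates the
chip effect, and `overall + median(value − probe_effect)` then lands
exactly in the jointly normalized space. (Storing bare row effects would
double-count the overall term and break that consistency.)

Quantile mapping replaces the value at rank k with the k-th reference
quantile; tied inputs receive the mean of the reference quantiles their
rank block spans, which keeps the operation idempotent. Re-processing the
original samples one at a time through the frozen model reproduces their
jointly normalized values to numerical precision. For a genuinely *new*
sample the frozen result differs from full joint re-normalization only
through the O(1/n) shift the new sample would itself induce in the
reference distribution — about 0.03 log2 units at n = 20 in simulation,
and vanishing at repository scale, which is the regime the frozen
approach is designed for.

## The synthetic generator

`simulate_collection()` draws
`x_gi = mu_g + delta·1[g in module(phenotype_i)] + b_{g,study_i} + eps_gi`
with `mu_g ~ N(7, 1.5²)` (a realistic log2 intensity scale),
disjoint planted modules, `b ~ N(0, sigma_b²)` per gene × study (a
per-study scalar mode is available), and Gaussian noise. Defaults —
2000 genes, 4 phenotypes × 25 samples, 10 studies, module size 40,
delta = 3, sigma_b = 0.7, sigma_e = 0.6 — encode the regime the package
is about: each planted gene's effect exceeds its batch shift, but
background genes outnumber planted ones ~12:1, so batch variation
dominates in aggregate. On all genes (or leading PCs) clustering then
tracks study; after variance-based selection the planted modules
dominate. A generator in which every single gene's batch shift exceeded
the biological effect would make variance-based selection uninformative by
construction and could not reproduce the contrast any method shows on
real collections.

The optional count mode treats the Gaussian surface as log2 expected
counts, draws negative-binomial counts (dispersion 0.1) and returns
log2-CPM — enough to exercise the Poisson-kernel scoring path.
`platform_transform()` applies a global strictly increasing map
`a + b(m + sign(x − m)|x − m|^gamma)`, preserving within-sample ranks, as
a stand-in for cross-platform intensity distortion.

What the generator does *not* emulate: probe-level microarray physics,
dropout/zero inflation, correlated (systematic, low-rank) batch effects,
overlapping or hierarchical phenotype modules, and class imbalance beyond
what the design grid expresses. Passing tests on these simulations
therefore demonstrates the algorithms' correctness and their behavior in
a controlled batch-vs-biology regime — not performance on any particular
real collection.

## Problem sizes and numerical conventions

The test and evaluation suites run at deliberate desk scale: collections
of 60–250 samples and 150–2000 genes, 200 reference + 50 held-out samples
for remapping recovery, 200–300 permutations and 150–200 null sets for
calibration checks, 10 seeds for replicate-based claims. These sizes were
chosen so the full evaluation recomputes in about a minute while leaving
every claimed property measurable; all of them scale up through ordinary
arguments.

Conventions collected in one place: variance uses n − 1; variance and
correlation ties break by gene id (stable radix sort); nearest-centroid
ties go to the lowest cluster id; annotation-vote ties return
`"ambiguous"`; mean-shift modes merge within bandwidth/2; affinity
calibration tolerance 1e-6; serialized maps print doubles as `%.17g` and
re-parse with strtod so round-trips are bit-exact; all stochastic stages
take explicit integer seeds and the remapping path is deterministic by
construction.

## Known limitations

- t-SNE coordinates have no absolute scale, so the mean-shift bandwidth
  interacts with sample count and perplexity; the 1.5/2.5 defaults are
  sensible for maps in the hundreds of samples but are parameters, not
  constants.
- Remapping quality degrades for subtypes thinly represented in the
  reference; the correlation diagnostics flag, but cannot repair, that
  situation.
- The enrichment scorer recomputes the kernel CDF from the analyzed
  matrix, so scores depend on the sample composition of the dataset being
  scored; comparing small focused studies to a large reference is the
  intended direction.
- Empirical p-values are bounded below by 1/n_permutations; with the
  default 1000 permutations, BH-adjusted calls at alpha = 0.001 rest on
  zero-count sets, which is why the pseudo-count column exists.
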
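---
title: "FES-k-means: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FES-k-means: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(feskmeans)
```

## The problem

Spatial epidemiology routinely needs to partition large georeferenced point
datasets — disease case locations, census-block prevalence records — into
homogeneous groups, and then to scrutinize the groups for the unusual
records that often carry the scientific signal.  k-means is the workhorse
partitioner, but its naive implementation computes `N * k` point-to-center
distances per iteration, and its online variants are sensitive to how fast
centers are allowed to move.

`feskmeans` implements a hybrid that attacks both issues at once:

* a **k-d tree** over the data accelerates the nearest-center assignment by
  pruning candidate centers for whole regions of space at a time, and
* **Mashor's decaying adaptation rate** damps the online center update so
  that centers move aggressively early and settle smoothly later.

The package also carries the two classical baselines (batch/Lloyd and
online/MacQueen k-means), the validity statistics used to compare them, a
box-plot outlier screen on distances to the assigned center, a subsampling
benchmark harness, and a synthetic-data generator, so the whole pipeline is
reproducible without any external dataset.

## Model and updates

Given records $x_1, \dots, x_N \in \mathbb{R}^d$ and $k$ centers $c_1,
\dots, c_k$, all methods minimize the within-class variance

$$ E = \sum_{i=1}^{k} \sum_{x_n \in C_i} \lVert x_n - c_i \rVert^2 . $$

**Lloyd** alternates a full nearest-center assignment with exact centroid
recomputation; its per-epoch MSE ($E/N$) is provably non-increasing.

**MacQueen** presents records one at a time; the winning center, having
absorbed $n_i$ records so far (its initializing record included), moves to
the running mean via $c_i \leftarrow c_i + (x - c_i)/n_i$.

**FES-k-means** also presents records sequentially, but the step size is a
global adaptation rate $\eta(t)$:

$$ c_i \leftarrow c_i + \eta(t)\,(x - c_i), \qquad
   \eta(t+1) = \frac{\eta(t)}{\exp\!\big(1/\sqrt{k + t}\big)} . $$

The schedule starts at $\eta(1) = \eta_0$ and decays strictly, fast at
first and ever more slowly (the decay factor tends to 1), which is exactly
the "large rate early, small steady-state rate late" behavior that makes
online k-means stable.

### Interpretation choices in the update rule

The published recurrence leaves three details open, which this package
fixes as follows (each is a single switch in the code if a different
reading is ever needed):

* `cluster_count` in the decay exponent is **k**, the number of clusters,
  not the winning cluster's membership count;
* $\eta$ decays **once per epoch** (full pass), not once per record — the
  schedule is time-indexed, and a per-record decay at realistic `N` would
  freeze the centers within a single pass ($\eta$ would shrink by
  $\exp(-\sum_{t\le N} 1/\sqrt{k+t}) \approx e^{-2\sqrt{N}}$);
* within an epoch, winners are computed against the centers **frozen at
  the start of the epoch** (a batch assignment), while the center updates
  themselves are applied sequentially in presentation order.  This makes
  the k-d tree acceleration exact: the tree-filtered assignment is
  contractually identical to a brute-force nearest-center scan, and the
  test suite holds the whole FES run (labels, centers, $\eta$ trace)
  bitwise equal to a tree-free reference implementation.

## The k-d tree and lossless filtering

`build_kdtree()` splits each cell — the tight bounding box of its points —
at the midpoint of its longest side (ties to the lowest dimension; points
on the boundary go left) and stops at `leaf_size` points (default 10) or
when all remaining points coincide.  Each node stores its point count and
coordinate sum.  Because cells are tightened to their points, the midpoint
of the longest side always separates the minimum from the maximum in that
dimension, so both children are non-empty and every splitting hyperplane
touches data; a sliding-midpoint fallback to the median is retained as a
defensive guard but is unreachable under tight cells.

`filter_assign()` walks the tree carrying a candidate list.  At each node
the candidate closest to the cell midpoint becomes the local winner; any
other candidate is discarded when no point of the cell can be strictly
closer to it than to the winner.  The discard test is exact: the
difference of squared distances to two centers is linear over the cell, so
it suffices to check the corner extremal in the direction
`candidate - winner`.  Exact ties go to the lower center index everywhere
(including exactly coincident centers, which are collapsed before the
walk), matching the brute-force tie-break.  When one candidate survives,
the whole subtree is assigned from the stored count and coordinate sum
without touching individual points — that is where the distance arithmetic
is saved.  The result object reports `n_dist_evals`, the number of
point-to-center distance evaluations actually performed (leaf evaluations
plus the per-epoch MSE pass), which on clustered data is a small fraction
of the brute-force `N * k * epochs`.

## Convergence tests

Each method stops at the first of: cluster membership unchanged from the
previous epoch; maximum per-center displacement within the epoch below
`epsilon` (default `1e-4`, coordinate units); for FES, relative MSE change
below `1e-8`; or `max_iter` epochs (default 20).  Dead centers — centers
owning no records — are kept in place and reported; the optional
`reseed_dead` flag relocates them to the record farthest from its nearest
center.

## Validation statistics

* `sse()` — the within-class variance above.
* `mse_db()` — `10 * log10(SSE/N)`.  The decibel convention for this
  power-like (squared-error) quantity is `10 log10`; a `20 log10` reading
  would simply double every value and difference, so the choice is fixed
  once here rather than fitted to anything.  A zero SSE is reported as
  `-Inf` with a warning.
* `davies_bouldin()` — per-cluster dispersions $e_i$ (mean *Euclidean*
  distance to the center, the classical $q = 1$ form), center distances
  $D_{ij}$, and the index $\frac{1}{k}\sum_i \max_{j \ne i}
  (e_i + e_j)/D_{ij}$.  Dead clusters are excluded (with a warning and a
  reduced $k$); coincident live centers are an error since the ratio is
  undefined.

## Outlier screen and benchmark protocol

`distance_outliers()` computes, per cluster, each member's distance to its
center and Tukey box-plot fences on those distances: quartiles by linear
interpolation of order statistics (`quantile(type = 7)`), upper fence
`Q3 + 1.5 * IQR`.  Distances are non-negative and right-skewed, so only the
upper fence flags records; clusters with fewer than four members get fences
but no flags.  The whisker rule is a package decision — the classical 1.5
IQR fence — stated once and tested against an independent order-statistic
computation.

`run_benchmark()` mirrors the evaluation protocol of processing 10%, 20%,
..., 100% of the data: for each fraction a seeded subsample without
replacement is drawn (the same subsample for all three methods) and each
method runs under an identical configuration, recording wall-clock runtime
and the final MSE in dB.  Runtimes are machine-bound and therefore
informational only; the tested speed property is the instrumented distance
-evaluation count, which is hardware-independent.

## The synthetic generator

`generate_blobs()` emulates the structure of the datasets this method
family is used on: isotropic Gaussian clusters in a coordinate box, at
full scale 10 clusters x 3,600 points in 2-D (36,000 records).  Two modes:

* **separable** (default): centers are rejected until pairwise separations
  reach at least 6 within-cluster standard deviations — ground truth is
  then essentially unambiguous;
* **hard**: unconstrained center placement, so clusters can run into each
  other at the edges.

Options add a density gradient (spread grows linearly with the center's
distance from the origin, `sd = base_spread * (0.5 + |c|/max|c|)`, so
clusters near the origin are concentrated) and appended Bernoulli(0.25)
indicator columns of the kind produced by binary exposure flags.  The
generative family is Gaussian by choice; real georeferenced data are
noisier, non-isotropic and spatially autocorrelated, so passing recovery
tests on these blobs demonstrates correctness of the machinery, not
performance guarantees on field data.

```{r example}
g <- generate_blobs(synth_spec(n_clusters = 10, points_per_cluster = 360,
                               base_spread = 2, seed = 1))
res <- fes_kmeans(g$points, run_config(k = 10, eta0 = 0.6, seed = 101))
res
```

## What the estimators can and cannot recover

A point worth stating precisely, because it governs what a recovery test
may legitimately assert.

With centers initialized at `k` records drawn uniformly from the data, the
probability that every one of `k` equal blobs receives exactly one initial
center is $k!/k^k$ — about 22% at $k = 3$ and effectively zero at
$k = 10$.  A blob with no center and a blob with two is a *stable local
optimum* for all three methods: nothing in the batch, running-mean or
decaying-rate update can split a doubled center across a wide gap once the
partition has stabilized.  This initialization sensitivity is the
classical weakness of k-means; the practice this package supports is to
choose `k` and the starting configuration from a prior data-reduction step
(for instance self-organizing-map training), which is outside the scope of
the package.  The two-cluster separated regime is the one setting where
batch k-means provably recovers the blobs from any distinct-records start,
and the test suite demonstrates exactly that.

Even with a perfect partition, the *reported centers* of the online
methods are not the cluster sample means:

* MacQueen's center is the running mean of everything it ever won,
  including records captured under an early bad configuration; with
  membership stabilizing after a few epochs, an initialization-history
  bias of order `separation * n_wrong / (n_wrong + epochs * n)` remains.
* The FES center is an exponentially weighted average with weight
  $\eta$; at the epoch where membership stabilizes, its residual noise is
  of order `sd * sqrt(eta/2)`, which exceeds the CLT band `3 * sd/sqrt(n)`
  unless the run continues until $\eta$ is very small.  On rare seeds the
  decaying rate can also freeze a split-blob configuration before the
  second center migrates across.

Consequently: the batch method's centers match the blob sample means to
CLT accuracy; the online methods' *partitions* match, and their cluster
means (recomputed from the partition) match, but their raw center vectors
carry the biases just described.  The test suite asserts the strict
raw-center statement for all three methods and therefore documents this
limitation as a failing expectation rather than hiding it.

## Numerical conventions

* All distance comparisons use squared Euclidean distances accumulated in
  the same dimension order on every code path, so tree and brute-force
  paths agree bitwise; reported distances are Euclidean.
* Ties — equidistant centers, equal box sides, equal nearest-neighbor
  distances — always resolve to the lowest index.
* Labels are `1..k` (R convention); empty clusters are reported as dead
  rather than renumbered.
* Every stochastic entry point (`init_centers`, `generate_blobs`,
  `run_benchmark`, shuffled presentation) takes an explicit seed and
  restores the caller's RNG state.

## Problem sizes used in the tests

The shipped suite exercises: oracle equivalence on ~1,200 randomized
nearest-neighbor instances across 1-16 dimensions; 50 seeded bitwise
comparisons of the tree-accelerated and brute-force FES paths; 100-instance
monotonicity sweeps; a 10-blob, 3,600-point delineation run; a 10,000-point
distance-evaluation count; and a 600-point, 30-record benchmark grid.
These sizes keep the full suite under a minute on one CPU while leaving
every property non-trivial; the generator scales to the full 36,000-point
configuration by changing one argument.

## Known limitations

* Initialization is uniform-from-data only; no k-means++ or SOM-based
  seeding, and no restarts.
* The k-d tree is static: no insertion, deletion or rebalancing, and no
  approximate queries.
* Only point data are supported (no lines or polygons), and GeoJSON export
  writes coordinates as given, without any CRS handling.
* `k` is user input; selecting it (e.g., via a validity-index sweep) is
  out of scope.
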
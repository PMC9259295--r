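---
title: "Distance-weighted kNN QSAR with simulated-annealing descriptor selection: methods and design"
author: "ccknn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ccknn methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccknn)
```

## The model

`ccknn` addresses descriptor-subset selection for QSAR tables: given a
compound × descriptor matrix with one continuous activity per compound, find
the small descriptor subspace in which nearest-neighbour structure predicts
activity best, and quantify that predictivity honestly.

The prediction engine is deliberately simple and local. In a candidate
subspace $S$ of $n$ descriptors, the distance between compounds $i$ and $j$
is the restricted Euclidean distance
$r_{ij} = \sqrt{\sum_{d \in S} (D_{id} - D_{jd})^2}$, and a compound's
activity is forecast as the weighted mean of its $k$ nearest neighbours,

$$\hat m = \sum_{i \in \mathrm{kNN}} w_i\, m_i,\qquad
  w_i = \frac{e^{-r_i}}{\sum_{j \in \mathrm{kNN}} e^{-r_j}},$$

so a nearer neighbour always carries a strictly greater weight, and the
prediction is a convex combination of neighbour activities (it can never
leave their range). Model quality is the leave-one-out cross-validated

$$q^2 = 1 - \frac{\sum_i (m_i - \hat m_i)^2}{\sum_i (m_i - \bar m)^2},$$

with $\bar m$ the mean activity of the **full** training set — the standard
LOO-$q^2$ convention. A per-fold denominator mean (excluding the held-out
compound) is a defensible alternative; it changes $q^2$ by $O(1/n^2)$ terms
and is not implemented.

The modelling assumptions are those of any kNN-QSAR: activity varies
smoothly (or at least locally consistently) in the selected descriptor
space; descriptors are informative after an affine per-column rescaling; and
the training compounds cover the region where predictions are requested. No
functional form is imposed on the activity surface.

## Range scaling

Raw descriptor columns routinely differ in scale by orders of magnitude, so
unscaled Euclidean distances would be dominated by the widest columns.
`rangeScale()` maps every column through $(x - \min)/(\max - \min)$ onto
$[0, 1]$ and records the per-column extrema in a `ScalingParams` object so
the identical transform can be replayed on external compounds
(`applyScaling()`); replayed values may fall outside $[0, 1]$ and are
deliberately not clipped, which keeps out-of-domain compounds visible.
Scaling is controlled by a single run-wide switch (default on) with an
optional per-column exemption list for users whose tables mix pre-normalized
descriptor families with raw ones; the package does not attempt to infer
descriptor provenance from names.

Constant columns map to all-zero rather than raising an error: the subset
search may legitimately sample them, they contribute nothing to any
distance, and aborting a long search over a degenerate column would be far
worse than a one-time warning.

## Choosing k

`sweepK()` evaluates $k = 1,\dots,k_{\max}$ and keeps the $k$ with the
highest $q^2$, breaking ties toward the smaller (more parsimonious) $k$.
The default $k_{\max} = 5$ reflects the common empirical finding that
distance-weighted kNN on QSAR-sized sets performs best with a handful of
neighbours; $k_{\max}$ is clamped to $n_\mathrm{compounds} - 1$ with a
message rather than an error so pipelines degrade gracefully on tiny sets.

## The annealing search

The subset of fixed size $n$ is optimised by classical Metropolis simulated
annealing with $q^2$ as the objective:

* **Move operator** — exchange `swapSize` (default 1) members for
  non-members, both chosen uniformly; every same-size subset is reachable.
* **Acceptance** — improving proposals always; worsening proposals with
  probability $\exp(\Delta q^2 / T)$.
* **Cooling** — geometric, derived so the temperature falls from `tInitial`
  (default 0.05) to `tFinal` (default $10^{-4}$) over the step budget
  (default 2000 proposals). Temperatures live on the $q^2$ scale: 0.05 makes
  a loss of 0.05 in $q^2$ acceptable with probability $e^{-1}$ early on,
  while $10^{-4}$ is effectively greedy.
* **Best tracking** — the best subset ever evaluated is returned (with its
  sweep-selected $k$) regardless of where the random walk ends.

Some methods under the "generalized simulated annealing" name use heavier
tailed (Tsallis) visiting distributions; without concrete visiting-
distribution parameters to implement, `ccknn` uses the classical Metropolis
form and says so. The stopping rule is a fixed step budget: "stop when the
highest $q^2$ is reached" is not operationally testable, and a budget plus
near-greedy final temperatures achieves the same intent reproducibly.

The subset size $n$ is an integer in $[1, n_\mathrm{descriptors}]$.
`runEnsemble()` repeats the search over a size grid (default
$\{10, 20, 30, 40, 50\}$ intersected with the valid range) with 10
independent restarts per size, the customary defence against both local
optima and over-interpretation of a single run. Per-member seeds are a
stable integer hash of (base seed, $n$, restart index), so adding restarts
never perturbs earlier members. An activity vector with zero variance makes
$q^2$ undefined for every subset; scoring maps it to $-\infty$, and
`anneal()` refuses to start since no subset can repair it.

`exhaustiveSearch()` enumerates all $\binom{p}{n}$ subsets (capped, default
$10^5$) in lexicographic order and is the package's own gold standard: on
small instances the annealer is expected to hit the exhaustive optimum in
essentially every seed, and the test suite asserts exactly that.

## Numerical choices

* **Neighbour ties** are broken by ascending compound index, everywhere
  (including inside the compiled scorer), so results are identical across
  runs and platforms. The $k$-sweep breaks $q^2$ ties toward smaller $k$;
  exhaustive search breaks subset ties lexicographically.
* **Weight underflow**: $e^{-r}$ underflows for $r \gtrsim 745$, which
  unscaled descriptor tables can easily produce. Weights are computed as
  $e^{-(r - r_{\min})}$ — identical after normalization, immune to 0/0.
* **Exact duplicates** (zero distance) need no special-casing: $e^{0} = 1$
  is finite; a duplicate receives the maximal weight but dominates only at
  $k = 1$.
* **The hot path** (`scoreSubset()`, `anneal()`, `exhaustiveSearch()`) runs
  a compiled k-sweep scorer (Rcpp) that computes plain sums of squared
  differences — no cross-product expansion of the distance, which would cost
  eight significant digits to cancellation — so it agrees with the R
  reference path (`looPredict()`, `sweepK()`) to machine precision, and the
  test suite checks both against a naive double-loop oracle at $10^{-12}$.
* **Serialized numbers** are written with 17 significant digits, making
  CSV/JSON round trips exact and repeated runs byte-identical.

## The synthetic benchmark generator

`simulateQsar()` emulates the shape of a QSAR table, not its chemistry:
descriptor columns are independent uniforms with per-column scales
log-spaced over a `scaleSpread` factor (default 100), so range scaling
genuinely matters; a random subset of columns is informative; activity is
built from the *unit-scale* latent values so every informative column
carries comparable signal regardless of its raw scale. Two response shapes
are provided: `linear` (weighted sum with weights drawn from `coefRange`,
random signs) because it is the simplest controllable truth, and `cluster`
(compounds scattered around a few centres in informative space, activity
equal to the centre's value) because local cluster structure is the regime
where neighbour-based prediction should beat a global fit. Gaussian noise is
added with SD equal to `noiseSd` times the noiseless activity SD, making
noise levels comparable across forms and seeds.

What the generator does **not** emulate: correlated descriptor families,
heavy-tailed or discrete descriptor distributions, activity cliffs, and
measurement error in descriptors. Passing recovery tests on this generator
therefore demonstrates that the search machinery works — not that any
particular real descriptor set will yield a predictive model.

`makeTwinFixture()` duplicates each compound under a second id; the
zero-distance twin makes $k = 1$ LOO exact and $q^2 = 1$ analytically, which
pins down the entire distance → weight → prediction → $q^2$ chain in tests.

## Problem sizes used in the tests

The suite exercises oracle equivalence on 20 random tables of up to 25
compounds × 12 descriptors; annealing-vs-exhaustive optimality on a
15-compound, 10-descriptor instance ($\binom{10}{2} = 45$ subsets, 2250
proposals, 20 seeds); planted-truth recovery at 60 compounds with 5
informative among 50 descriptors and 25% noise (20 generator seeds, 10
restarts each); and a full default-grid ensemble (5 sizes × 10 restarts) on
a 120 × 60 table with a shortened 100-proposal budget per restart. These
sizes were chosen as the smallest that still make each property
statistically meaningful.

## Known limitations

* Only the $e^{-r}$ kernel and the Euclidean metric are provided; no
  Minkowski generalization, no tunable kernel width.
* No applicability-domain estimate accompanies external predictions;
  out-of-range compounds are visible only through their unclipped scaled
  values.
* No significance testing of the selected model (e.g. y-scrambling); a high
  $q^2$ after an aggressive subset search can still be optimistic, and an
  external test set remains the only honest check.
* Missing descriptor values are rejected, not imputed.
* Activity must be continuous; classification endpoints are out of scope.
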
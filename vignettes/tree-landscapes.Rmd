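---
title: "Tree landscapes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree landscapes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloscape)
```

# The problem

Genome-scale phylogenetics routinely produces thousands of competing
trees: bootstrap replicates of many gene partitions, each favoring its
own topology.  A consensus tree compresses all of that into one diagram
and discards the structure of the disagreement.  A *tree landscape* keeps
it: every tree becomes a point in 2 or 3 dimensions, placed so that
Euclidean distances between points approximate Robinson–Foulds (RF)
distances between topologies.  Clusters then reveal which partitions
agree, outliers flag analytical problems, and landscapes from different
taxon sets can be compared geometrically.

`phyloscape` implements that stack end to end: RF distance matrices over
Newick tree sets, four nonlinear dimensionality reduction (NLDR) stress
functions with five optimizers, intrinsic-dimensionality estimation,
embedding diagnostics, and convex-hull summaries of partition clusters.

# Distances

The RF distance between two unrooted topologies is the size of the
symmetric difference of their non-trivial bipartition (split) sets.  We
report the raw split count, unnormalized; `normalize = TRUE` divides by
the maximum 2(n − 3).  Two conventions exist in the wild (some software
halves the count); all downstream embeddings are invariant to a global
scale factor, up to step-size tuning, so the choice is cosmetic — but the
matrix reader (`read_distance_matrix()`) accepts any externally computed
metric if another convention or distance is wanted.

Splits are encoded as canonical 0/1 membership strings over the
lexicographically sorted leaf set, complemented so the first leaf is
always on the 0 side; split-set operations are then exact string
comparisons.  `rf_matrix()` pools splits across trees into a dictionary
and obtains all pairwise shared-split counts from one cross-product of
the tree-by-split incidence matrix, which keeps thousands of trees
practical.  Duplicate topologies are retained, producing legitimate zero
off-diagonal distances that the stress functions must (and do) handle.

# Stress functions

With input dissimilarities $\delta_{ij}$ and embedded distances $d_{ij}$,
sums over unordered pairs $i<j$:

* **Normalized stress** $\sum(\delta-d)^2 / \sum\delta^2$
* **Kruskal-1 stress** $\sqrt{\sum(\delta-d)^2 / \sum d^2}$
* **Sammon/NLM stress** $(1/\sum'\delta)\sum'(\delta-d)^2/\delta$, the
  primed sums skipping $\delta = 0$ pairs (duplicate topologies)
* **CCA stress** $\sum(\delta-d)^2\,F(d,\lambda)$ with the step weight
  $F(d,\lambda)=\mathbf 1\{d \le \lambda\}$

The CCA weight depends on the *output* distance: once a pair has drifted
apart beyond the neighborhood radius $\lambda$, its error stops counting.
That is what lets a CCA embedding "tear" a high-dimensional manifold
while preserving local structure, and it is also why raw CCA stress
values are not comparable across runs with different $\lambda$
schedules.  $\lambda$ decays geometrically per optimizer sweep from
`cca_lambda0` (default: max $\delta$) to `cca_lambda_end` (default: 5%
of max $\delta$).  A smooth decay weight would be a drop-in alternative;
the step form is the classical choice and the default here.

Analytic gradients are provided for all four (for CCA the step weight is
held piecewise-constant; the subgradient at the discontinuity takes the
interior branch) and are verified against central finite differences in
the test suite.

# Optimizers and the 14 pairings

* **Majorization (SMACOF)** — each sweep applies the Guttman transform,
  the exact minimizer of the quadratic majorizer of the weighted
  squared-error stress (weights 1, or $1/\delta$ for NLM).  Descent of
  the majorized objective is guaranteed and asserted; for the Kruskal-1
  pairing the reported final stress is the Kruskal-1 value of the final
  configuration, while the monotone trace is the surrogate objective
  (the square-root ratio itself carries no monotonicity guarantee).
* **Gauss–Seidel–Newton** — cycles point by point, applying a damped
  Newton step from the analytic gradient and a diagonal Gauss–Newton
  Hessian of the stress restricted to that point, in place; steps that
  would increase the stress are halved up to 10 times, and unusable
  curvature falls back to a safeguarded gradient step.
* **SGD** — for normalized/NLM, visits all pairs in seeded random order
  with step schedule $\alpha_t=\alpha_0/(1+t/\tau)$; for CCA, visits
  every point as a pivot and moves all others along the connecting
  direction (the classical curvilinear-components update).
* **MCMC simulated annealing** — Metropolis over single-point Gaussian
  perturbations, geometric cooling, returning the best state ever
  visited (the chain may wander after finding a minimum).
* **Linear iteration** — fixed-step steepest descent on Kruskal-1 with
  no line search; descent is *not* guaranteed and upticks in the trace
  are recorded, not errors.

Of the 16 stress-optimizer combinations, majorization+CCA and
Gauss–Seidel+CCA are excluded and SGD+Kruskal-1 is replaced by the
linear iteration, leaving the 14 admissible pairings that
`admissible_pairs()` returns and `run_batch()` enforces.  The exclusions
are honored as stated rather than re-derived.  `run_batch()` implements
the replicate protocol: 10 restarts by default from different seeded
initial configurations, with mean and standard error of the final
stresses and the best run identified.

## Hyperparameter choices

NLDR hyperparameters are artifact choices; these defaults were selected
so that every admissible pairing recovers exactly-embeddable instances
on the property-test suite, and all are exposed via `optimizer_spec()`:

* Convergence: relative stress change below `tol` = 1e-6 over 10
  consecutive sweeps (robust to SGD noise), with an absolute floor of
  1e-14 so runs that reach machine-zero stress terminate.
* SGD: $\alpha_0 = 0.2$, $\tau = 100$ sweeps.  NLM's $1/\delta$ pair
  weights are normalized to unit mean and capped at 10×: raw
  $1/\delta$ steps diverge when near-duplicate trees make some
  $\delta$ tiny.
* MCMC: $T_0 = 0.1 \times$ initial stress$/N$.  The unscaled stress$/N$
  is far hotter than the typical single-point stress change —
  especially for Kruskal-1, whose square root compresses changes — and
  leaves the chain diffusing for most of the budget.  The proposal sd
  starts at 5% of the coordinate range and adapts to the acceptance
  rate (grown above 30%, shrunk below 20%), the standard adaptive
  annealing practice; a fixed sd cannot both explore early and refine
  late.  Cooling stays at the classical 0.99 per sweep.
* Linear iteration: $\eta = 0.3$ in units of the squared mean positive
  dissimilarity, making the step invariant to a global rescaling of
  the input distances; 0.05 in these units converges too slowly to be
  useful.  Divergence is detected by coordinate-spread blow-up (5× the
  data diameter) as well as stress explosion, because an oversized step
  on Kruskal-1 inflates the configuration while the stress saturates
  below 1 instead of diverging.

# Intrinsic dimensionality

Whether a 2D or 3D landscape can be faithful depends on the intrinsic
dimensionality of the distance matrix.  Four routes are implemented:

* **Correlation dimension** — slope of $\log C(r)$ against $\log r$,
  with $C(r)$ the fraction of pairs closer than $r$.  RF distances are
  integers, so the radius grid uses quantiles of the *distinct* observed
  distances (20 points).  The default quantile range is 2%–25%: the
  $r^D$ scaling law holds only at radii small against the diameter of
  the support, and including upper-percentile radii (where $C(r)$
  saturates toward 1) biases the slope low by tens of percent — enough
  to miss a 3-cube's dimension by more than the estimator's own
  sampling error.
* **Maximum likelihood (Levina–Bickel)** — inverse mean log-ratio of
  neighbor distances, averaged over points and over $k \in [6, 12]$
  (the range its authors recommend).  Zero neighbor distances (duplicate
  topologies) are excluded per point.
* **Nearest-neighbor (Pettis)** — slope of $\log k$ on $\log \bar r_k$
  with the iterated Gamma-function bias correction; both the raw and the
  iterated value are reported, the iterated one as the headline.
* **Stress-versus-dimension curve** — best final stress of a chosen
  pairing (default CCA+SGD) at each candidate dimension.  The elbow is
  classically read by eye; `stress_vs_dimension()` always returns the
  full curve and operationalizes the visual call as the smallest
  dimension within 5% of the stress at the largest dimension probed.

All three point estimators recover $d \in \{1,2,3\}$ within ±25% on
seeded 1000-point manifold samples, and are invariant to a global
rescaling of the distances.

# Diagnostics

`trustworthiness()` penalizes spurious neighbors the embedding
introduces; `continuity()` penalizes true neighbors it loses (tearing a
cluster costs continuity before trustworthiness).  Both are rank-based,
lie in [0, 1], and equal 1 exactly for rank-preserving embeddings.  Rank
ties — frequent with integer RF distances — are broken by point index,
deterministically.  The neighborhood size is not canonical; the default
is $k = 5$ and reports cover $k \in \{1, 5, 10, 20\}$.

`one_nn()` is implemented as nearest-neighbor partition-label agreement:
the fraction of trees whose nearest neighbor carries the same partition
label, with the same statistic on the input distances reported alongside
as the ceiling.  The measure needs at least two labels.

`procrustes()` performs ordinary Procrustes superimposition (translation,
orthogonal transform including reflections, scale); the residual is
normalized by the centered reference's total sum of squares, so it lies
in [0, 1].  `equivalence_classes()` compares replicate embeddings:
a run is non-equivalent when its median residual to the others exceeds
Q3 + 1.5 IQR of all pairwise residuals — an operationalization of
"very large relative to the others".  With two runs the rule is
undefined and both are reported as one class with a warning.

# Hull summaries

`hull_summary()` encloses each partition's retained points in a convex
hull after variance-threshold outlier pruning, deliberately avoiding a
strict statistical interpretation (no confidence ellipses).

**Pruning.**  A point is an outlier if excluding it drops the variance of
the pairwise distances by more than `tau` (default 0.01).  The drop is
read as a *relative* decrease — an absolute reading would make the
threshold scale-dependent — with `absolute = TRUE` providing the other
reading, and a centroid-based variance behind `centroid_based = TRUE`.
Removal is greedy, one point at a time (largest drop first, ties to the
lowest index), matching the iterative phrasing and staying
deterministic.  Two properties are worth knowing: pruning is idempotent,
and at `tau = 1` nothing is ever removed.  The relative reading
interacts with group size: leave-one-out drops in a cluster of ~20
points sit at several percent even when no outlier is present, so small
groups need a larger `tau` (or the absolute reading) if pruning is meant
to remove only gross outliers.

**Hulls.**  2D hulls use the standard planar algorithm; 3D hulls are an
incremental triangulated hull built in-package (no qhull binding exists
in the dependency set).  Exactly coplanar exterior points (cube corners)
are resolved by a deterministic 1e-9-scale symbolic perturbation; facet
indices always refer to the original coordinates.  Degenerate groups —
collinear, coplanar in 3D, or fewer than p+1 points — fall back to a
lower-dimensional hull and are flagged.

**Separation.**  `separate_hulls()` translates each group rigidly by `s`
units along the ray from the center of all points to the group centroid,
revealing hulls hidden near the origin.  Within-group distances are
preserved up to one floating-point rounding of each coordinate (a
stronger, bit-exact guarantee is not attainable in double precision) and
the operation is reversed by `-s`.  A sensible sequence of `s` values
for presentation is 0, 0.5, 1 and 2 times the mean hull radius.

# Synthetic landscapes

`simulate_landscape()` generates the statistical structure multi-gene
bootstrap studies exhibit, so the whole pipeline is testable without
external data.  Each partition has a center topology; member trees apply
a Poisson number of random NNI moves to it, with expected count
`rate_scale / length`.  The defaults state a realistic world: 20 taxa,
5 partitions with length proxies 200–1800 (short to long mitochondrial
genes), 100 trees per partition (one per bootstrap replicate), and
`rate_scale = 2000`, so a 200-site partition averages 10 NNI moves per
tree and an 1800-site one about one — shorter partitions carry fewer
informative characters and scatter more widely.  `mode = "null"` shares
a single center across partitions, emulating partitions that differ only
by sampling error.

What the generator does *not* emulate: sequence resampling, likelihood
tree search, or any correlation between partitions beyond the shared or
distinct centers.  A green end-to-end test therefore establishes that
the pipeline recovers NNI-ball cluster structure of realistic size and
spread — not that it reproduces any published empirical landscape.

`random_tree()` draws uniformly over unrooted binary topologies by
sequential random leaf attachment; `sample_manifold()` supplies seeded
segment/square/cube/Gaussian/swiss-roll samples with known dimension for
the estimator tests.

# Numerical edge cases

* Coincident points ($d_{ij}=0$): gradient contributions are zeroed (the
  spherically symmetric subgradient), and the SGD pair step skips them.
* Duplicate topologies ($\delta_{ij}=0$): excluded from NLM sums,
  included elsewhere.
* All-zero distance matrices are rejected as degenerate wherever a
  normalizer would vanish.
* Incremental single-point stress accumulators (GSN, MCMC) are clamped
  at zero to absorb floating-point drift near perfect embeddings.

# A worked example

```{r example, eval = FALSE}
ts <- simulate_landscape(base_seed = 1)        # 5 partitions, 500 trees
dm <- rf_matrix(ts)
batch <- run_batch(dm, "cca", "sgd", p = 3, n_restarts = 3, base_seed = 1,
                   opt = optimizer_spec(max_sweeps = 150))
best <- batch$runs[[batch$best]]
one_nn(best, ts$partition)        # ~0.98: clusters kept together
trustworthiness(dm, best, 5)      # ~0.94: few spurious neighbors
hs <- hull_summary(best$X, ts$partition, tau = 0.01)
plot(separate_hulls(hs, 5))
```

# Known limitations

* Only the RF metric is computed natively; other tree distances enter
  through the matrix reader.
* The hull renderer draws 3D hulls by their 2D silhouette; there is no
  interactive 3D output.
* All matrices are dense; memory is quadratic in the number of trees
  (about 50M entries near 7,000 trees is the practical comfort zone).
* The pruning threshold's relative reading is group-size sensitive for
  small groups, as discussed above.
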
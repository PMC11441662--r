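---
title: "Edge-centric overlapping modules in weighted functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-centric overlapping modules in weighted functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overlapnet)
```

## The problem

Classical module detection assigns every brain region to exactly one
community, yet association regions plainly participate in several
functional systems at once.  `overlapnet` takes the edge-centric view:
communities are detected among the *connections* of a weighted functional
network, and a region inherits a graded, possibly overlapping module
profile from the assignments of its incident edges.  The package
implements the full analysis chain — network thresholding, edge-graph
construction, consensus module detection, nodal overlap quantification,
longitudinal age-effect modelling and SVR prediction — and ships a
synthetic-cohort generator with planted ground truth so that every stage
can be validated end to end without access to restricted MRI data.

## From correlation matrix to edge graph

A per-scan Pearson correlation matrix is thresholded at a connection
density $d$ (default 0.15): the $E = \lceil d \, N(N-1)/2 \rceil$
strongest positive correlations are kept as weights, negatives are
discarded.  The ceiling convention reproduces the standard count of 4,020
edges for $N = 232$ at 15% density.  Ties at the cut are broken by node
pair order and logged; they essentially never occur in real-valued data
but matter for block-constant toy matrices.

Each retained edge becomes a vertex of the *edge graph*.  Two edges
$e_{ik}$ and $e_{jk}$ sharing node $k$ are linked by the Tanimoto
similarity of the *modified connectivity profiles* of their non-shared
endpoints,

$$S(e_{ik}, e_{jk}) = \frac{a_i \cdot a_j}
  {|a_i|^2 + |a_j|^2 - a_i \cdot a_j},$$

where $a_i$ is row $i$ of the thresholded adjacency matrix with the
diagonal entry replaced by the node's mean edge weight.  The nonzero
diagonal keeps $S$ well defined when $i$ and $j$ are themselves
connected.  Edge pairs without a common node get similarity zero; the
construction enumerates incident-edge pairs per node ($O(\sum_i k_i^2)$)
and is verified in the tests against a naive all-pairs oracle.  $S$ is
invariant to a global rescaling of the weights, so the pipeline does not
depend on the overall magnitude of the correlations.

## Module detection and consensus

Modules in the edge graph are found by weighted-modularity Louvain
optimization (`igraph`), with the vertex visiting order shuffled under a
seed: a fixed seed is exactly reproducible and different seeds explore
different local optima.  Because single Louvain runs vary, the module
number of a network is taken as the most frequent count over an ensemble
(default 100 instances), with ties broken toward the smaller number;
entropy and modularity are averaged across instances.  The resolution
parameter is fixed at 1 (classic Newman–Girvan objective) and exposed as
an argument.

For group-level maps a consensus partition is computed: the ensemble's
module co-occurrence matrix (fraction of instances co-assigning each edge
pair) is itself treated as a weighted graph and re-clustered, iterating
until every instance of an iteration returns the same partition up to
relabelling (cap 20 iterations; non-convergence returns the most frequent
partition with a warning).  The co-occurrence matrix is clustered as-is,
without thresholding.  On planted block structures with noise
$\sigma \le 0.05$ the consensus recovers the blocks exactly, and the
procedure is idempotent once stable.

## Nodal overlap

For node $i$ with $k_i$ edges, $p_{ik}$ is the fraction of its edges in
module $k$.  The overlap measure is the normalized Shannon entropy

$$H_i = -\frac{1}{\log_2 n_i} \sum_{k} p_{ik} \log_2 p_{ik},$$

where $n_i$ is the number of modules the node's own edges touch (not the
global module count), $0 \log 0 := 0$, and a single-module node has
$H_i = 0$ by convention ($0/0 := 0$).  A node is an *overlapping region*
when $n_i \ge 2$.  Normalization happens before instance averaging.
Edgeless nodes propagate as missing and are excluded from all means —
never silently zero-filled.  Per-module spatial maps, cross-group module
matching by maximal Pearson spatial correlation (many-to-one allowed) and
functional-system summaries (membership = any positive proportion by
default, threshold configurable) complete the topography toolkit.

## Longitudinal age effects

Developmental change in any scalar measure $y_{ij}$ (subject $i$, scan
$j$) is estimated with mixed-effects models fitted by maximum likelihood
(`lmerTest`):

- linear: $y_{ij} = \beta_0 + b_i + (\beta_{age} + b_{age,i})\,age_{ij} +
  \beta_{sex}\,sex_i + \beta_{mFD}\,mFD_{ij} + \varepsilon_{ij}$
- quadratic: adds fixed and random $age^2$ terms.

Random effects are independent (diagonal covariance); age is entered in
years, uncentered, and sex as 0/1.  These choices are conventional
defaults — fixed-effect inference is unaffected by centering, and the
data rarely identify an intercept–slope covariance at 1–3 scans per
subject.  On optimizer non-convergence the model falls back to a random
intercept only, recording the ladder step.  The better model per measure
is chosen by AIC (ties to the linear model); the reported t and p come
from the chosen model's highest-order age term with Satterthwaite degrees
of freedom, and node-wise p-values are corrected by Benjamini–Hochberg.
Calibration is checked by simulation: the fixed-age test's type-I error
over 500 null cohorts of 200 subjects lies in [3%, 7%] at $\alpha =
0.05$, and planted slopes are covered by their 95% CIs at the nominal
rate.

## Spatial-autocorrelation-preserving surrogates

Spatial maps are compared with a permutation null that preserves spatial
autocorrelation.  Each surrogate permutes the map, smooths it with
Gaussian distance kernels over a grid of five log-spaced bandwidths
(spanning the 5th–90th distance percentiles), blends the smoothed field
with the raw permutation at ratios 1–0.5 to tune the short-range noise
level, selects the candidate minimizing relative squared error against
the original's 10-bin empirical variogram, and restores the original
value multiset exactly by rank remapping.  An unsmoothed candidate is
always in the grid, so spatially white maps fall back to plain
permutations.  Surrogates of smooth planted maps (coordinate gradients,
curved fields) match the original variogram within 20% at every lag; a
map that is a pure gradient along one axis of the sampling lattice is the
hardest case, since a trend has no sill.  The corrected correlation test
reports the plain Pearson r with the add-one permutation p-value,
two-sided by default.

## SVR prediction pipelines

Chronological age is predicted from per-scan nodal entropy maps with
linear $\varepsilon$-SVR (`e1071`, libsvm; C = 1, $\varepsilon$ = 0.1).
One scan per subject is drawn at random so longitudinal scans never
straddle the train/test split; folds are age-stratified by sorting ages
and dealing consecutive blocks round-robin (the goal — similar fold age
distributions — is stated by the method, the dealing algorithm is ours);
features are min–max scaled on the training folds only (verified by an
outlier-injection test); accuracy is the Pearson r between pooled
out-of-fold predictions and true ages, with a shuffled-target permutation
null and the add-one p estimator.  Scan selection is repeated (default
1,000) to average out sampling noise, and a whole-sample refit yields
primal coefficients as per-node contribution weights, averaged over
repeats, with positive and negative weights aggregated separately per
functional system.  Before prediction, sex, mFD and subject-specific
random effects can be regressed out of each nodal measure via the mixed
model, retaining the fixed-age signal.

Per-scan entropy maps are predicted from six structural features
(cortical volume, thickness, curvature, folding index, surface area,
FA strength — the latter is the row sum of a mean-FA connection matrix).
Here *nodes* are the cross-validation items: random 10-fold splits within
the scan, same scaling and accuracy conventions (scaling in this pipeline
mirrors the age pipeline and can be disabled).  The null shuffles entropy
across nodes per scan (default 100 times) and pools null accuracies over
scans; a scan is significant when its observed r exceeds the pooled 95th
percentile.

## The synthetic generator

The generator produces every input the analysis consumes, with truth
recorded beside the data and full reproducibility from (parameters,
seed):

- **Networks**: nodes get one primary module (contiguous blocks, default
  7 modules over 232 nodes) and a fraction (default 0.3) a second random
  membership; correlations are `between + within * shared-membership
  fraction + symmetric Gaussian noise` (defaults 0.05, 0.6, sd 0.05),
  clipped, unit diagonal.  The defaults put the within-block pair
  fraction near the 15% retention density, giving clean planted
  modules whose dual-membership nodes are the overlapping regions.
- **Cohorts**: 305 subjects with the 166/92/47 mix of 1/2/3 scans (491
  scans), baseline ages uniform on 6–14 years, follow-ups one year apart
  with sd 0.1 jitter, sex Bernoulli(0.5), mFD lognormal (median 0.12 mm,
  capped at the 0.5 mm exclusion ceiling), measures drawn from the linear
  mixed model above with configurable per-node slopes (default 0.02/yr),
  random-effect sds (0.05, 0.01) and residual sd 0.05 — magnitudes chosen
  so that measures live on the entropy scale.
- **Structural features**: `loading * standardized entropy + noise`, with
  the thickness analog loading positive and the other five negative
  (sd 0.8, giving univariate |r| near 0.6).
- **Coordinates**: golden-spiral points on an 80 mm sphere with a small
  seeded jitter, for distance-based surrogate tests.

What the generator does *not* emulate: real fMRI noise spectra and
motion artifacts, geometric cortical folding, distance-dependent
connection weights, and hemispheric structure.  Passing tests therefore
demonstrate that the algorithms recover what they are defined to recover
under the stated generative assumptions — not that the biological
findings would replicate in any particular cohort.

## Problem sizes and numerical choices

The validation suite runs planted 232-node networks for the density and
module-number checks, 60-node networks (10 seeds, 12 instances) for the
entropy–truth contrast, 20-seed consensus recovery on 24-edge planted
graphs, 500 + 100 simulated cohorts of 200 subjects for mixed-model
calibration, 40–50 replicates per prediction-calibration check, and a
446-scan × 100-shuffle pooled null (20 nodes per scan) for the
aggregation count — sizes at which each property is statistically
informative while the whole suite stays desk-scale.  Degenerate inputs
are handled explicitly: empty edge graphs and both-zero profiles raise
typed errors, constant features scale to zero with a warning, constant
maps cannot be permuted into surrogates, and edgeless nodes stay missing
throughout.

## Known limitations

Indirect edge relationships (edge pairs without a common node) are
ignored by construction.  The Louvain resolution, consensus convergence
rule (all instances identical) and modal-number tie rule are conventions
exposed as arguments, not estimated quantities.  The surrogate
generator's bandwidth grid is fixed rather than optimized per map.
Eigenspectral detection, GAMM trajectories and repeated-measures ANOVA
are out of scope, as are all MRI preprocessing steps; FA strength is
consumed from a precomputed matrix.
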
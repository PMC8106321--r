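---
title: "Village-level prevalence mapping: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Village-level prevalence mapping: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(villagessl)
```

## The estimation problem

Household surveys measure child anthropometric failure — stunting,
underweight and wasting, each a binary indicator of a z-score below −2
against a growth reference — in a few tens of thousands of sampled
clusters, while the census enumerates hundreds of thousands of villages
with rich demographic and amenity attributes but no health outcomes.
Two obstacles prevent treating this as ordinary supervised regression:

1. **Displaced coordinates.** Cluster GPS locations are randomly
   displaced for confidentiality (up to 5 km for rural clusters, up to
   10 km for 1% of them, always within the district), so a cluster can
   only be linked to a *set* of candidate villages — a many-to-many
   fuzzy correspondence.
2. **Scarce reliable labels.** After spatial linkage, only a handful of
   villages are matched one-to-one by a cluster; the overwhelming
   majority of villages carry no label at all.

`villagessl` implements a pipeline for this setting: hierarchical
shrinkage estimation of cluster prevalences, fuzzy spatial linkage,
graph-harmonic semisupervised regression seeded by the reliable label
set, and an iterative bias-correction that progressively assigns the
fuzzy cluster labels to their best-matching candidate villages.  A
synthetic-country generator reproduces the statistical structure of the
real data (which are restricted-access) so that every stage can be
exercised and tested end to end.

## Cluster prevalence: four-level logistic shrinkage

Child $i$ in cluster $j$, district $k$, state $l$ is modelled as

$$\mathrm{logit}(\pi_{ijkl}) = \beta + u_{jkl} + v_{kl} + f_l,
\qquad u \sim N(0, \sigma^2_u),\; v \sim N(0, \sigma^2_v),\;
f \sim N(0, \sigma^2_f),$$

with the conventional latent individual-level variance $\pi^2/3$
(`latent_level1_variance()`).  Cluster prevalences are posterior means
of $\mathrm{logit}^{-1}(\beta + u_{jkl} + v_{kl} + f_l)$ over the
monitored draws, which shrinks noisy small-cluster proportions toward
the grand mean in proportion to their imprecision.

Because the model contains no child-level covariates, the Bernoulli
likelihood collapses exactly to one binomial term per cluster;
`fit_multilevel()` aggregates child records to these sufficient
statistics before sampling.  The sampler is random-walk
Metropolis-within-Gibbs, vectorized over the units of each level, with:

* diffuse priors — $N(0, 10^6)$ on $\beta$, inverse-Gamma(0.001, 0.001)
  on each variance (conjugate Gibbs draws);
* step sizes adapted toward 44% acceptance during burn-in only;
* **interweaving sweeps** after each scan: exact Gibbs moves along the
  directions $(\beta, f)$, $(f, v)$ and $(v, u)$ that shift mass between
  adjacent levels while leaving every linear predictor unchanged.
  Without these, the intercept mixes extremely slowly (it is confounded
  with the mean of the state effects) and its posterior intervals
  undercover; with them, simulation coverage of all four parameters is
  nominal (see `test-acceptance.R`);
* starting values from method-of-moments on empirical logits, after
  clamping raw proportions to $[10^{-6}, 1-10^{-6}]$;
* defaults of 500 burn-in and 5,000 monitored iterations
  (`mcmc_settings()`), with a warning when the effective sample size of
  any variance chain falls below 100.

A level observed with a single unit has its variance fixed at zero with
a warning rather than failing.

## Variance partitioning

`fit_variance_decomposition()` partitions a village-level quantity (on
the percentage scale) with a three-level random-intercept linear model
fitted by REML via glmmTMB; the village component is the residual
variance, and standard errors of the variance components come from the
TMB sdreport by the delta method on the log-sd scale.  The coefficients

$$\mathrm{VPC}_z = \frac{\sigma^2_z}
{\sigma^2_{state} + \sigma^2_{district} + \sigma^2_{village}}
\times 100$$

are reported to 0.1 (`compute_vpc()`).  The denominator is deliberately
the three-level *geographic* total: the individual-level $\pi^2/3$
convention belongs to the four-level binary model and is not part of
the geographic decomposition.

## Fuzzy spatial linkage

`link_clusters()` reproduces the five linkage steps: Thiessen (Voronoi)
polygons represent village boundaries within each district
(`thiessen_polygons()`); clusters are buffered by the maximum ordinary
displacement radius (5 km, configurable; the 1% of clusters displaced
up to 10 km are knowingly under-buffered, matching the accepted
mismatch in the source design); buffers are overlaid with village
polygons (boundary touching counts, a conservative inclusion rule);
pairs are filtered to same-district, both-rural matches where the
village population strictly exceeds the cluster population; duplicates
are dissolved.  Clusters with exactly one surviving candidate village
form the **reliable label set** $L_0$ — when several such clusters hit
the same village, their estimates are averaged unweighted — and the
remaining clusters form the fuzzy set $C$ with candidate lists $V_c$.

## Harmonic semisupervised regression

`build_graph()` standardizes the village feature matrix (constant
columns dropped), builds the union-symmetrized $k$-nearest-neighbor
graph under Euclidean distance ($k = 10$ by default) and weights edges
with a Gaussian kernel whose bandwidth defaults to the median included
edge distance.  `harmonic_solve()` clamps labeled villages and solves
the graph-Laplacian subsystem over unlabeled villages with conjugate
gradients (tolerance $10^{-8}$), so every unlabeled village's value is
the weighted average of its neighbors' values.  This expresses both
standard semisupervised assumptions: the *cluster assumption* (feature-
similar villages have similar prevalences) through the graph, and the
*harmonic approximation* through the interpolation.  The cited joint
harmonic-function estimator is not fully specified in the source
article; this module implements the pure harmonic core and exposes an
optional ridge term $\lambda$ on the unlabeled diagonal (default 0)
for ill-conditioned graphs, which is the documented stand-in.

Numerical conventions: solutions are clamped to
$[\min(\text{labels}), \max(\text{labels})]$, which removes
solver-tolerance dust so the discrete maximum principle holds exactly;
components containing no labeled village receive the global labeled
mean (logged); predictions stay on the probability scale throughout —
no logit transform is needed because the maximum principle already
confines them to the label range.

## Bias-corrected iteration

`run_bias_corrected()` alternates harmonic solves with a correction
step for $T$ rounds (default 5):

1. solve from the current labeled set ($L_0$ at the start);
2. for each fuzzy cluster $c$, pick
   $j^\* = \arg\min_{j \in V_c} |Y_j - Y_C[c]|$ and assign the
   cluster's value to that village;
3. revert the $L_0$ villages to their original reliable labels;
4. re-solve from the enlarged labeled set.

Determinism conventions: ties in the gap go to the smallest village
index; when two clusters select the same village the smaller gap wins,
then the smaller cluster index; the graph is built once and reused
across iterations (features do not change).  The published iterative
description reverts "to $L_1$" where the single-pass version reverts
"to $L_0$"; the package reads this as reverting the reliable villages
to their *original* labels in every iteration — the only reading under
which the reliable set retains its meaning.  With this convention
$|L_t| \le m + |C|$ always, the reliable labels are reproduced exactly
in the output, and a problem whose clusters all map one-to-one is a
fixed point after the first round.

## The synthetic country

`synthetic_config()` defines the study conditions; the defaults are
chosen once to emulate the rural-India setting at desk scale:

* **Hierarchy and geometry.** 4 states × 3 districts × 60 villages
  (720 villages, scaled down from ~600k) on planar kilometer
  coordinates: states are tiled blocks, districts are 25 km squares,
  villages are uniform points whose clipped Voronoi cells serve as
  polygons.  Rectangular districts keep every clipping operation exact
  for convex geometry; the planar simplification preserves exactly the
  topological facts the method uses (containment, adjacency, distance).
* **Features.** $d = 40$ census-style features: half Bernoulli amenity
  flags (school, road, power, ... presence), half Beta-distributed
  proportions (literacy, worker share, ...), both with district-level
  heterogeneity, as real amenity data are spatially autocorrelated.
* **True prevalences.**
  $\mathrm{logit}(p) = \beta + w'(x - \bar{x}) + f + v + u$ with
  variances $(\sigma^2_f, \sigma^2_v, \sigma^2_u) = (0.3, 0.1, 0.6)$ —
  most variation at the village level — and a sparse effect vector $w$
  (5 active features, magnitude 0.8, alternating sign) giving a
  feature-driven logit variance of about 0.7, comparable to the village
  component, so the cluster assumption genuinely holds.  Centering the
  feature effect at the national mean makes the baselines
  $(-0.62, -0.79, -1.61)$ control national prevalence directly,
  giving means near 38% / 35% / 22% for stunting / underweight /
  wasting.
* **Survey.** 25% of villages surveyed (simple random sampling; the
  estimation stage is model-based and never uses design weights), 10-40
  children per cluster (the real per-cluster counts distribution is not
  published; this range is configurable), binomial failures at the true
  prevalences, cluster population uniform on [1, village population].
* **Displacement.** Uniform angle, uniform distance on $[0, R]$ with
  $R = 10$ km with probability 0.01 and 5 km otherwise; candidates
  outside the district are rejected and redrawn, with the radius halved
  per retry after 100 failures (guaranteeing termination), and the true
  location as a logged last resort.

What the generator does *not* emulate: geodetic coordinates, urban
areas, probability-proportional-to-size sampling, measurement error in
anthropometry, and spatial correlation of the village random effects
beyond the district/state nesting.  Passing tests therefore demonstrate
the pipeline's statistical correctness under its own assumptions, not
performance on real census/DHS data.

## Descriptive summaries and sensitivity analyses

`area_summaries()` produces district/state means, SDs and interquartile
ranges, national equal-count deciles and dense within-district,
within-state and national ranks (rank 1 = highest burden).  Quantiles
use the median-unbiased convention (type 8) and decile ties break by
village id, making every ranking deterministic across platforms.

Three sensitivity analyses mirror the published checks:
`random_label_robustness()` re-runs the full iteration from random
initial assignments of villages to cluster indicators and compares
prediction quartiles (the package's stability tolerance defaults to 2
percentage points — the published check is visual);
`range_vs_cluster_size()` verifies that prediction ranges grow with
candidate-set size; `district_aggregation_correlation()` correlates
district means of predictions with district means of the labeled
cluster estimates.

## Problem sizes used by the test suite

The acceptance experiments run at sizes chosen to keep Monte-Carlo
noise well inside each tolerance: parameter recovery uses 20 replicates
of a 30 × 5 × 20 × 25 design (burn-in 300 / 2,000 monitored — the
production default of 500 / 5,000 is unnecessary for interval coverage
at this size); the three-level decomposition recovery uses 600 states ×
10 × 10 (the state-level variance is the binding constraint: its
sampling s.d. over $G$ groups scales as $\sqrt{2/G}$); the
bias-correction improvement experiment averages 20 pipeline seeds at
the default country size; the sensitivity suite runs one 4 × 3 × 150
country (1,800 villages, ~19 candidate villages per cluster, close to
the real pair density) because quartile stability across random
assignments is an absolute 2-point tolerance whose Monte-Carlo noise
shrinks with country size.

## Known limitations

* Village-level predictions carry no uncertainty intervals; there is no
  straightforward way to compute them in this label-assignment setting,
  and none are provided.
* The harmonic solution compresses the prediction distribution toward
  the label mean — village-level dispersion is underestimated even when
  district-level aggregates agree well with the labeled clusters.
* Geometry routines assume convex district polygons (always true for
  the synthetic generator); non-convex administrative boundaries would
  require a general clipping library.
* The linkage radius deliberately stays at 5 km although 1% of
  clusters are displaced farther; those clusters can miss their true
  source village among their candidates.
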
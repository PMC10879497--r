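---
title: "Methods: longitudinal brain-network trajectories with netaging"
author: "netaging authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal brain-network trajectories with netaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netaging)
```

## The scientific problem

In aging mammals the functional connectome tends to *de-differentiate*:
correlations within well-defined networks (modules) weaken while
correlations between modules strengthen, so the boundaries of the network
architecture blur. Longitudinal resting-state fMRI in mice makes this
process observable over most of an adult lifespan — scans at roughly 12, 18
and 24 months of age, with exact ages recorded in days. `netaging`
implements the full analysis chain for such a design:

1. **Connectivity.** Per session, average BOLD time series per atlas ROI (72
   bilateral ROIs: 36 regions x 2 hemispheres) are correlated (Pearson r)
   and Fisher z-transformed into a symmetric 72 x 72 matrix **Z**; sessions
   of the same subject and time point are averaged. The non-negative part
   **Z+** feeds all module detection and thresholding.
2. **Consensus modules.** Fine-tuned Louvain clustering of **Z+**, repeated
   with random sweep orders; agreement matrices re-clustered to a
   subject-level and then a group-level consensus; a resolution sweep
   (gamma 1.0–2.0 in steps of 0.1) with selection of the gamma whose group
   partition has the greatest mean normalized mutual information (NMI) with
   the other sweep points.
3. **Segregation.** The segregation index
   \(SI = (\bar z_\mathrm{within} - \bar z_\mathrm{between}) / \bar z_\mathrm{within}\)
   over positive edges, either over all modules or over the three most
   reliably classified modules (SI3), always using the module classification
   obtained at the first (12-month) time point. Subjects whose SI3 stays
   below 0.43 at both of the first two time points are flagged and excluded
   from downstream statistics.
4. **Graph metrics.** Density thresholding of **Z+** at 16 densities from
   0.10 to 0.25; six global metrics (clustering coefficient, characteristic
   path length, local efficiency, small-world index, modularity,
   assortativity) and four nodal metrics (degree, betweenness, nodal
   efficiency, clustering), each averaged over the thresholds at which it is
   defined, with left/right hemisphere values combined per region.
5. **Trajectory statistics.** Linear mixed-effects models
   `outcome ~ 1 + Age * Factor + (1 | subject)` fitted by maximum
   likelihood with exact age in days, a time effect as an equal-weight
   contrast over factor levels, Benjamini–Hochberg FDR over edge/region
   families, and two-sample Kolmogorov–Smirnov comparisons of slope
   distributions.

## The synthetic cohort generator

Because the pipeline is validated without imaging data, `cohortSpec()`
describes a cohort whose *ground truth* is known, and `simulateCohort()`
realizes it:

* **Structure.** 72 ROIs in consecutive left/right pairs, six planted
  modules of 12 ROIs each (bilateral by construction); a block-structured
  target correlation matrix (`targetCorrelationMatrix()`) with baseline
  within-module correlation 0.5 and between-module correlation 0.1, chosen
  so the Fisher-z contrast (about 0.55 vs 0.10) matches what cortical
  networks show in practice.
* **Design.** Two cohorts (one per trajectory group) of both sexes, four
  subjects per sex-by-cohort cell (16 subjects), target ages 365/548/730
  days jittered uniformly by up to ±14 days, two sessions of 415 usable
  volumes per time point, and 12% dropout before each later time point —
  the attrition rate a well-run longitudinal mouse study achieves.
* **Aging.** Correlations change linearly in days (the trajectory models
  are linear in exact age): group X loses within-module correlation at
  1.5e-4 per day and gains between-module correlation at 1e-4 per day, so
  its planted SI3 declines by roughly 0.1 between 12 and 24 months — the
  magnitude of decline a de-differentiating cohort shows; group Y is flat.
  These effect sizes are configurable and are calibration choices, not
  published values. A per-subject Gaussian offset (sd 0.02) is added to
  both correlations, creating the between-subject level differences that
  the random intercepts absorb.
* **Noise model.** Volumes are drawn i.i.d. Gaussian with the target
  correlation (an optional AR(1) coefficient, default 0, adds temporal
  autocorrelation). Since the pipeline consumes only Pearson correlations,
  autocorrelation would only inflate the sampling variance of the
  correlation estimates; it is exposed for robustness experiments rather
  than as a default.

What the generator deliberately does **not** emulate: hemodynamics, motion
and scanner artifacts, anesthesia effects, non-Gaussian BOLD noise,
spatially heterogeneous module strength, and negative true correlations.
Passing tests therefore demonstrate that the *analysis chain* is correct
and well calibrated on data with known truth — not that real mouse data
meet the generator's assumptions.

## Numerical and algorithmic choices

**Louvain and its fine-tuning.** `louvainOnce()` is a dense-matrix
implementation (C++) of two-phase Louvain maximizing
\(Q(\gamma) = \tfrac{1}{2m}\sum_{ij}[W_{ij} - \gamma k_i k_j/2m]\,\delta(c_i,c_j)\)
(the \(i=j\) null term included), with the node sweep order randomized by
the seed, single-node moves into empty communities allowed, and a
fine-tuning loop that alternates single-node reassignment with
re-aggregation until Q stops improving. On exhaustively enumerable graphs
(≤ 8 nodes) a single run never exceeds the true maximum and attains it on
the large majority of seeds; like every greedy modularity maximizer
(igraph's multilevel implementation behaves the same way) it can stall in
local optima on dense unstructured graphs. The pipeline compensates in two
distinct ways: the consensus machinery aggregates 100–1000 independent
runs, and the *modularity metric* takes the best of 10 restarts in which
restarts 2–10 start from random initial partitions — restarts from
all-singletons tend to fall into a single basin on small graphs, whereas
random initial partitions explore distinct basins and restore agreement
with the exhaustive maximum.

**Consensus clustering.** Before an agreement matrix is re-clustered, the
expected co-assignment under the permutation null (the mean off-diagonal
agreement) is subtracted and negative entries floored at zero. This is the
standard null correction of consensus clustering and replaces a hard
agreement threshold, which would add an arbitrary parameter; the iteration
stops when all repetitions agree (cap 50, with a diagnostic error).
Re-clustering uses the same gamma as the originating sweep point, keeping
each sweep point self-consistent. Module ids are ordered by descending
module size (ties by lowest contained node index), and the "first three"
modules of the SI3 are resolved as the three modules with the highest mean
classification consistency — i.e. the most reliable ones.

**NMI.** Normalization by the arithmetic mean of the entropies,
\(2I/(H_1+H_2)\); when both partitions have zero entropy the value is
defined as 1, when exactly one has zero entropy as 0. The implementation is
cross-checked against igraph's independent NMI in the tests. Gamma
selection aggregates by the mean pairwise NMI of each gamma's group
partition against all others, with ties broken toward the smaller gamma.

**Module matching.** Classification consistency matches each repetition's
modules to the consensus modules by maximal overlap, solved exactly with a
small Hungarian assignment (O(k³) shortest augmenting paths) on the
contingency table, validated against exhaustive permutation search.

**Connectivity conventions.** Correlations with |r| ≥ 1 − 1e-7 are clipped
before `atanh` (duplicated series must not crash the pipeline); the
diagonal is stored as zero and excluded everywhere; the edge-wise
group-level test is a one-sample t against zero with a one-sided upper-tail
p (the displayed quantity is presence of connectivity), FDR-corrected over
the upper-triangle family only; edges with zero across-subject variance are
recorded as degenerate (p = 0 or 1 by the sign of the mean) with a warning
rather than NaN.

**Segregation conventions.** "Positive correlations only" is implemented
by *excluding* non-positive edges from both means; the alternative of
zeroing them into the denominator (which deflates both means by counting
non-edges) is available as `negativePolicy = "zero"`. With no positive
between-module edge the between mean is 0 and SI = 1; with no positive
within-module edge the SI is undefined and the row is flagged, never
silently dropped. SI3 restricts the computation to the subgraph of the
selected modules (edges to excluded modules are ignored). The exclusion
rule flags a subject when SI3 < 0.43 (strict) at *all* of the early time
points at which it was scanned.

**Thresholding.** The density grid is 16 evenly spaced values from 0.10 to
0.25 (step 0.01): a 16-value grid and those endpoints jointly determine the
step. The `ceiling(density · n(n−1)/2)` strongest positive edges are kept,
with ties broken by ascending upper-triangle index so graphs are
reproducible. Synthetic graphs can disconnect at low densities; the
characteristic path length is then computed over connected pairs and the
graph flagged, and undefined metrics (assortativity on regular graphs, the
small-world index when the rewired null has zero clustering) are excluded
from threshold averaging with their count recorded.

**Small-world null.** Sigma uses 10 degree-preserving double-edge-swap
rewirings per graph (seeded); the choice of null model is a comparability
caveat, as toolboxes differ here.

**Mixed models.** Fitted with lme4 by maximum likelihood. Age is centered
at the grand mean (so factor main effects are interpretable at the average
age) and rescaled to months for conditioning; slopes are reported per day
and per month. Factors are treatment-coded with female / group X as
reference. Wald t statistics use residual degrees of freedom (observations
minus fixed effects) — the convention that matches df values reported
alongside t in this literature; Satterthwaite approximations are out of
scope. The time effect in factor models is the equal-weight contrast
`age + ½ · age:factor`, with variance from the coefficient covariance.
Betweenness enters the nodal models unnormalized; normalization would only
rescale the units of its t statistics.

## Validation problem sizes

The test suite validates each stage against independent oracles: exhaustive
enumeration of connected graphs through 5 nodes plus sampled 6–7-node
graphs for every global and nodal metric (Floyd–Warshall distances, path
enumeration for betweenness, exhaustive partition search for modularity);
planted-partition recovery with 20 synthetic subjects, 72 ROIs and a full
gamma sweep at 100 repetitions over 10 master seeds (NMI ≥ 0.9 against the
planted partition in at least 9); SI3 slope recovery over 20 simulated
cohorts at the generator defaults; LME calibration over 200 parameter
recovery and 200 null replicates; BH against a brute-force step-up oracle
on 1000 random p-vectors; and byte-identical reruns of the full pipeline
under a fixed seed. The repetition counts (100 rather than 1000) and
replicate numbers are chosen so the whole suite validates the same
machinery at sizes a laptop handles comfortably; the repetition count is a
config field and scales to the reference analysis's 1000 unchanged.

## Known limitations

* Real printed statistics of any particular animal cohort are not
  reproducible from synthetic data; the pipeline reproduces *procedures*
  and is validated by recovery of planted truth.
* Greedy modularity maximization is heuristic; single runs can miss the
  global optimum on small dense graphs (see above).
* The sigma small-world index depends on the rewired-null convention.
* Overlapping or hierarchical community structure, weighted-graph metric
  variants, and rich-club/participation coefficients are out of scope.
* Spatial (anatomical) plotting of modules is out of scope; partitions are
  exported as tables.
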
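# netaging

Longitudinal functional brain-network analysis for aging cohorts.

`netaging` is an R package for studying how the functional connectome of an
aging brain reorganizes over time, built for longitudinal resting-state
fMRI designs in which the same subjects (here: mice, scanned at roughly 12,
18 and 24 months of age) are followed across most of the adult lifespan. It
is aimed at researchers who have ROI-level time series or precomputed
connectivity matrices plus a cohort table, and who want a reproducible,
seed-driven path from those inputs to module structure, segregation
trajectories and graph-metric statistics. A synthetic-cohort generator with
planted ground truth makes the entire pipeline testable without any imaging
data.

## What it computes

* **Connectivity**: Pearson correlations between ROI time series, Fisher
  z-transform (`Z`), session averaging, the positive part `Z+`, and
  edge-wise one-sample group tests with FDR control.
* **Consensus modules**: fine-tuned Louvain clustering of `Z+` maximizing
  the resolution-adjusted modularity
  `Q(γ) = (1/2m) Σᵢⱼ [Wᵢⱼ − γ kᵢkⱼ/2m] δ(cᵢ,cⱼ)`, repeated with random
  sweep orders; agreement matrices re-clustered to subject- and group-level
  consensus partitions; a γ-sweep (1.0–2.0, step 0.1) selecting the most
  representative partition by mean pairwise normalized mutual information;
  per-node classification consistency and module flow across time points.
* **Segregation**: the segregation index
  `SI = (mean within − mean between) / mean within` over positive z edges,
  over all modules or the three most reliable ones (SI3), always using the
  baseline (12-month) module classification; exclusion flagging of subjects
  with SI3 < 0.43 at the early time points.
* **Graph metrics**: density thresholding (16 densities, 0.10–0.25), six
  global and four nodal metrics averaged over thresholds, bilateral
  (left/right) combination per region.
* **Trajectory statistics**: linear mixed-effects models
  `outcome ~ 1 + Age * Factor + (1 | subject)` (maximum likelihood, exact
  age in days), equal-weight time contrasts, mass-univariate fits with
  Benjamini–Hochberg FDR, and Kolmogorov–Smirnov comparisons of slope
  distributions.

## A worked example

Simulate a small cohort (8 subjects, two trajectory groups, 72 bilateral
ROIs with 6 planted modules), detect modules at baseline, and fit the SI3
aging trajectory of the de-segregating group:

```r
library(netaging)

spec <- cohortSpec(nSubjectsPerCell = 2L, seed = 7L)
spec
#> CohortSpec: 8 subjects (2 per sex x cohort cell), cohorts [A=Y, B=X]
#>   72 ROIs, 6 planted modules; timepoints (days): 365, 548, 730
#>   r0 within/between 0.50/0.10, dropout 0.12, subject sd 0.020

sim <- simulateCohortConnectivity(spec, seed = 7)
sim$matrices[[1]]
#> ConnectivityMatrix: 72 x 72 ROIs | subject s001 | timepoint 12mo | 2 session(s)
#>   z range [-0.077, 0.617], mean 0.128

base <- sim$matrices[vapply(sim$matrices,
                            function(m) m@timepointLabel == "12mo",
                            logical(1))]
sw <- gammaSweep(base, gammas = seq(1, 2, 0.5), nReps = 50, seed = 7)
sw
#> Resolution sweep: 1, 1.5, 2
#> selected gamma = 1.00 (6 modules, mean NMI 1.000)

si3 <- siTrajectories(sim$matrices, sw$selectedPartition, sim$design,
                      moduleSubset = 1:3)
fitLME(si3[si3$group == "X", ], outcome = "si", factor = "none")
#> LME (ML): si ~ age  + (1 | subject)
#>   4 subjects, 12 observations, df = 10
#>         term estimate        se      t         p estimate_per_day
#>  (Intercept)  0.75285 0.0076009 99.048 2.695e-16        0.7528541
#>         .age -0.00875 0.0008962 -9.764 1.978e-06       -0.0002875
```

Reading the output: the sweep recovers the six planted modules perfectly
(NMI 1.0 between all resolutions, tie resolved to γ = 1). Group X was
simulated to de-segregate, and its fitted SI3 slope is −0.00875 per month
(−2.9e-4 per day, t = −9.8): the three-module segregation index falls by
about 0.1 over the year between 12 and 24 months, matching the planted
effect. The group-Y fit (not shown) is flat.

`runPipeline(runConfig(seed = ...))` runs all stages end to end and writes
matrices, partitions, segregation tables, metric tables, statistics and a
manifest (config hash, seed, row counts) into an output directory; the run
is byte-for-byte reproducible for a fixed config and seed. A thin
command-line wrapper is provided in `inst/scripts/netaging.R`.

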
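---
title: "Causal structural covariance networks: model, generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal structural covariance networks: model, generator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `cascnet`, the design of
its synthetic-study generator, and the numerical choices made in the
implementation, together with their known limitations. Every quantitative
property claimed here is exercised by the package's test suite; nothing below
is asserted without a corresponding computation in `tests/testthat/`.

## 1. The analysis model

### 1.1 Pseudo-time from lesion burden

The central assumption is that, in a cross-sectional cohort of patients with
white-matter hyperintensities (WMH), lesion volume indexes disease
progression. Sorting patients by ascending WMH volume therefore turns the
collection of cross-sectional grey-matter maps into a pseudo-time series: the
map of the patient with the next-larger lesion load is treated as the "next
time point" of a progressing process. `build_pseudo_timeseries()` implements
this as

1. residualize each grey-matter feature on nuisance covariates (age, sex,
   education, total intracranial volume) by per-feature least squares;
2. order the patient rows by ascending `wmh_volume`, ties broken by
   `subject_id` so the ordering is total and reproducible.

This is an ordering assumption, not a measurement of time: it is only as good
as the monotone relationship between lesion burden and progression, and
between-subject variability enters the series as noise.

### 1.2 Signed Granger causality on the pseudo-time series

For a seed series $x_t$ and a target series $y_t$ (both z-standardized), the
signed causal weight is the least-squares coefficient $\beta$ in

$$ y_t = \alpha + \rho\, y_{t-1} + \beta\, x_{t-1} + \varepsilon_t . $$

`signed_gc_pair()` returns $\beta$: positive values mean grey-matter decline
at the seed precedes decline at the target (propagation), negative values
mean decline at the seed precedes relative increase at the target
(compensation). `voxelwise_cascn()` computes this for every in-mask voxel in
both directions (seed as driver, seed as receiver) and z-scores each map over
its defined voxels. The vectorized implementation solves the 2x2 normal
equations in closed form per voxel; the test suite verifies equality with an
explicit `lm()` refit to 1e-10.

Voxels whose series are nearly collinear with the seed — the seed's own
voxels and partial-volume neighbours — have non-identifiable lag-1
coefficients that can dominate both the observed map and the permutation
null. They are excluded when their contemporaneous correlation with the seed
exceeds `seed_cor_max` (default 0.8). Because the exclusion is computed from
contemporaneous correlations it is invariant under reordering of the
pseudo-time index, so it does not break the exchangeability of the
permutation null described next.

### 1.3 Thresholding and cluster-level inference

Following the conventional criteria for this analysis, voxels pass if
$|z| > 1.96$ and $|\mathrm{GC}| > 0.20$; supra-threshold voxels are grouped by
26-connectivity and clusters must exceed `min_cluster_voxels`. Cluster
p-values come from a permutation null of the maximum cluster mass (sum of
$|z|$ over the cluster): the pseudo-time index is randomly reordered,
destroying any lagged structure while preserving the marginal distribution of
every voxel series, and the maximal supra-threshold cluster mass is recorded
per permutation. The p-value uses the add-one estimator $(1 + \#\{M_b \ge
m\})/(B + 1)$, and Benjamini–Hochberg FDR is applied across clusters.

The default extent of 200 voxels is meaningful at full MRI resolution. The
package's synthetic grid is $24^3$ with radius-2 planted regions
(about 33 voxels), so all shipped analyses use a desk-scale profile with
`min_cluster_voxels = 10`; this is a grid-scale choice, not a tuning
parameter.

The group (patient vs control) voxel-wise contrast uses the same cluster
machinery with a per-voxel GLM t statistic for the group coefficient
(covariates in the design) and group-label permutation as the null.

### 1.4 Severity staging

`fit_stage_thresholds()` smooths global grey-matter volume against WMH volume
with loess (locally quadratic) and approximates the smoothed curve with a
continuous four-segment piecewise-linear function by exhaustive least-squares
search over a candidate grid of three interior breakpoints. The breakpoints
are the stage thresholds; `assign_stages()` uses right-closed intervals
(stage I $= [0, t_1]$, II $= (t_1, t_2]$, and so on). A Fazekas-based
grouping (`group_by_fazekas()`, identity mapping of grades 1–3 to stages
I–III) is provided for comparison. Breakpoint recovery accuracy is limited by
the loess smoothing bias at curvature changes plus the candidate-grid
resolution; the test suite demonstrates recovery within 1 mL on a planted
four-segment curve.

### 1.5 Network metrics

ROI-level graphs (`roi_gc_matrix()`) retain ordered pairs with
$|\mathrm{GC}| > 0.20$ as signed directed edges. Degree metrics count binary
and weighted ($|\mathrm{GC}|$) in/out degree; nodes with positive binary
out-minus-in degree are causal sources, negative are targets. Community
structure maximizes the Leicht–Newman directed weighted modularity

$$ Q = \frac{1}{m} \sum_{ij} \left[ A_{ij} - \frac{s_i^{out} s_j^{in}}{m}
\right] \delta(c_i, c_j), \qquad A = |\mathrm{GC}|, $$

exhaustively over all set partitions for graphs with up to 10 nodes and by
greedy agglomeration plus single-node refinement above that. The test suite
checks $Q$ against `igraph::modularity()` and the optimizer against full
enumeration on graphs with up to 8 nodes.

### 1.6 Mediation

`fit_paths()` standardizes exposure (WMH), mediator (global GMV) and outcome
(DST or 1/TMT-A; the reciprocal aligns the direction of "better"), then fits
`M ~ X + C` and `Y ~ X + M + C` by least squares. The indirect effect is
$a \cdot b$ and the total effect $c' + ab$, which equals the X coefficient of
the reduced-form regression exactly (an algebraic identity of nested
least-squares fits, checked to 1e-10). Confidence intervals use a
case-resampling bootstrap with bias-corrected percentile endpoints (the
median-bias correction $z_0$, without acceleration); significance is interval
exclusion of zero. Coverage for the indirect effect at $n = 500$ is measured
in the test suite.

## 2. The synthetic generator

Real cohort data for this design are not redistributable, so the package
ships a generator whose defaults *are* the study conditions: 185 patients, 40
controls, and marginals calibrated to the published cohort description.

### 2.1 Cohort calibration

* **Lesion volumes** are lognormal with `meanlog = log(5.24)` and
  `sdlog = (log 11.68 - log 2.64) / (2 qnorm(0.75))`, i.e. quantile-matched
  to the published median and interquartile range. Sampling is stratified
  (systematic inverse-CDF: one draw per probability stratum of width $1/n$,
  randomly permuted and jittered). Plain iid sampling of a heavy-tailed
  lognormal leaves the *sample* median with a standard deviation of about
  0.5 mL at $n = 185$, which would defeat calibration checks; stratification
  pins every cohort's quantiles to the target distribution at $O(1/n)$ while
  keeping draws random.
* **Global grey-matter volume** is linear in sample-standardized raw WMH
  volume with correlation $-0.954$ plus independent Gaussian residue, then
  scaled to the published patient mean and SD. The coupling is planted on the
  raw (not log) lesion volume because the analysis measures the raw-scale
  Pearson correlation; a generator coupling only log-lesion to volume caps
  the raw correlation near `cor(X, log X)` of the lognormal (about 0.72) and
  cannot reach the published value.
* **Fazekas grades** are keyed to lognormal volume cutoffs at the cumulative
  published grade proportions, making grade monotone in volume.
* **Cognition** follows the planted path structure on standardized scales:
  $z(\text{score}) = c' z(\text{WMH}) + b\, z(\text{GMV}) + \text{noise}$,
  with the residual SD chosen so the standardized score has unit variance
  given the realised WMH–GMV correlation. DST is mapped to the published
  patient mean/SD. 1/TMT-A is generated the same way on the reciprocal scale
  (delta-method scale calibration) and inverted to seconds.

### 2.2 Images and planted propagation

Each subject's image is a smooth radial density template (Gaussian of scale 7
voxels on a $24^3$ grid, 6 mm isotropic), scaled to the subject's global
grey-matter volume; the analysis mask is template $> 0.27$. Patients lose
density in the planted source region following
`atrophy_slope * log1p(wmh)` plus a region-level innovation
(`signal_noise_sd`), and each target region gains or loses `weight` times the
*realised* (noisy) source deficit of the patient `lag` positions earlier in
the WMH-ascending order. Using the realised series rather than the noise-free
trend is essential: lag-1 Granger causality identifies the propagation
through the innovations, while a shared noise-free monotone trend makes every
region series mutually predictive and destroys directionality. The default
innovation scale (0.25 density units) was chosen from seeded sweeps so that
the planted source is recovered as the strongest causal hub and the planted
two-module structure is recovered with adjusted Rand index at least 0.9 in
well over 90% of runs; the test suite re-measures both on 50 fresh seeds.

The default truth plants a source plus five targets at source-relative lags
1–5 with signs (+, +, −, −, −), so the effective lag-1 causal graph is a
six-node chain splitting into a propagation module and a compensation module
with the source as the unique strongest sender. Note that a lag-1 *seed*
map can only detect lag-1 neighbours of the seed — deeper chain members are
driven by innovations unseen by the seed at lag 1 — so voxel-level recovery
tests use a truth with lag-1 positive and negative targets, while the chain
is assessed at ROI level where each link is lag-1.

Independent Gaussian voxel noise is added last and values are clamped to
$[0, 1.5]$. Smoothing is available (`fwhm_vox`) but off by default: the
planted regions are already spatially coherent, and smoothing blurs region
boundaries that the cluster-extent tests rely on.

## 3. Numerical choices

* **Closed-form GC**: the per-voxel lag-1 regression is solved via 2x2
  normal equations after within-window centering, vectorized across voxels;
  column standardization is permutation-invariant and is computed once per
  map, not per permutation.
* **Connected components** are found by building the 26-neighbour adjacency
  over supra-threshold voxels (half-offset enumeration, each undirected pair
  once) and running `igraph::components()`.
* **Permutation p-values** use the add-one estimator, so the smallest
  attainable p with $B$ permutations is $1/(B+1)$; defaults use $B \ge 200$.
* **Pooled-variance t** (not Welch) is used for the summary-statistics group
  comparisons, because it reproduces the published demographic statistics.
* **Determinism**: every stochastic step takes an explicit integer seed;
  pipeline sub-stages derive their seeds from the run seed by fixed offsets.
  Identical configurations produce byte-identical result bundles.

## 4. Limitations

* The pseudo-time construction assumes lesion burden is a valid progression
  index; violations (fast progressors with small lesions) appear as noise or
  bias that the method cannot distinguish from true propagation.
* Lag-1 seed maps are blind to influences at deeper lags (Section 2.2).
* The generated TMT-A seconds have a heavier right tail than the published
  SD suggests: the reciprocal transform of a calibrated 1/TMT-A inflates the
  seconds-scale SD. Only DST is used for score-scale calibration checks.
* The published GMV group t statistic (8.200) recomputes to 8.201 from the
  two-decimal published summaries; the original was evidently computed from
  unrounded data. The package reproduces the published TIV and chi-square
  statistics exactly from the same summaries.
* Greedy modularity above 10 nodes is a heuristic; it is exact only where
  exhaustive search is feasible, and the shipped analyses stay within that
  range.

## 5. Reproducing an analysis

```{r, eval = FALSE}
library(cascnet)

# full pipeline at study scale
bundle <- run_full_pipeline(pipeline_config(seed = 1, out_dir = "results"))

# or stage by stage
sim <- simulate_study(185, 40, seed = 1)
pts <- build_pseudo_timeseries(sim$images, sim$cohort)
seed_series <- extract_seed_series(pts, sim$truth$source_roi)
maps <- voxelwise_cascn(pts, seed_series, seed = sim$truth$source_roi,
                        config = analysis_config(min_cluster_voxels = 10,
                                                 n_perm = 200))
clusters <- threshold_cascn(maps$seed_to_target, pts, seed_series,
                            analysis_config(min_cluster_voxels = 10), seed = 1)
```

The numbered scripts under `analysis/` run the same stages as thin drivers
and write plain-text tables under `results/`.
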
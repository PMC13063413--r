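---
title: "Benchmarking biodegradation rate constants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking biodegradation rate constants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rembench)
```

## The problem and the model

A first-order biodegradation rate constant *k* (d⁻¹) measured for one
chemical varies strongly between aquatic systems and between sampling
times, because the composition and function of the degrading microbial
community varies. `rembench` quantifies how much of that spatiotemporal
variability can be removed by *chemical benchmarking*: dividing each
chemical's rate constant by that of a reference chemical measured in the
same site-experiment, on the assumption that the two chemicals' relative
reactivity is constant in space and time.

All analysis happens on log10 *k*. The unit of observation is the
*site-experiment* — one incubation with water and sediment from one
location at one sampling time — and seasonal repeats at a location are
separate site-experiments, so one standard deviation pools spatial and
temporal variability deliberately. For chemical *i* with valid rate
constants at *N* sites,

* `stddev_i` = sample standard deviation (N − 1 denominator) of
  log10 k over those sites (`chemical_stddev()`);
* the benchmarked series is log10 k′ = log10 k_i − log10 k_BM at sites
  where both are valid, and its residuals are deviations from the mean of
  those differences (`benchmark_residuals()`);
* `REM_i = stddev_i − stddev'_i` (`rem()`), positive when benchmarking
  tightened the chemical's spread.

Mean-centering the benchmarked series stands in for the reference-site
ratio k_i,ref / k_BM,ref: a stddev-based efficacy measure is invariant to
that constant, so the ratio is never estimated separately.

### The gap rule, and one deliberate reading

Rate constants that are not significantly different from zero are treated
as missing, so the benchmark can be missing at sites where the chemical is
not. There, the chemical's *own* residual (log10 k minus its mean over all
its valid sites) fills the missing benchmarked residual, and `stddev'` is
computed as `sqrt(sum(r²) / (N − 1))` over the pooled residual set with
*N* the chemical's total valid-site count.

Two details here are genuinely open and were fixed once:

* the pooled residual set is **not re-centered** after gap residuals are
  added. The filled quantities are already deviations, so re-subtracting a
  pooled mean would double-center the shared-site part. With no gaps the
  two readings coincide exactly.
* the mean used for the shared-site residuals is taken over shared sites
  only, while the gap residuals deviate from the chemical's mean over all
  its valid sites — the most literal reading of "the residual from log k
  fills the missing residual of log k′".

The brute-force transcription used as the equation-level oracle in the
test suite implements the same reading independently; the choice itself is
a modelling decision, not something the oracle can adjudicate.

### Benchmark selection

`select_benchmark()` tries every pool member as benchmark for the rest and
keeps the largest median REM; ties break to the lexicographically smallest
chemical id so runs are deterministic. `run_ubm()` does this over all
chemicals; `run_gbm()` independently within each group, pooling the
summary over groups. Benchmark chemicals have no per-chemical entry and
are excluded from every summary median — a benchmark trivially achieves
stddev′ = 0 against itself and would inflate the statistics.

`min_n = 3` valid sites is required for any stddev: the N − 1 denominator
needs two, and three keeps two-point stddevs from dominating medians. It
is an argument everywhere it applies.

## Preprocessing

Order of operations: dissolved-fraction correction, pH correction, log10
transform and pivot, per-chemical IQR outlier removal, coverage filter.
The corrections are multiplicative, so they commute; they run first so the
outlier test sees corrected values.

* **Sorption**: `k / f_dissolved` references the rate constant to the
  freely dissolved pool (`dissolved_correct()`).
* **pH speciation**: `ph_correct()` rescales by the ratio of
  Henderson–Hasselbalch neutral fractions at the reference pH (default 7)
  and the experimental pH. Multiprotic chemicals use the independent-site
  product approximation; the correction is known to overcorrect somewhat
  in reality, so no exactness beyond the monoprotic closed form is
  claimed.
* **Outliers**: per chemical, across all site-experiments, on log10 k,
  with Tukey fences at 1.5 × IQR. Quartiles use linear interpolation of
  order statistics (R's default type 7) — fences depend on the quantile
  convention, so it is fixed and stated. Fewer than 4 values: nothing is
  flagged. Zero IQR: values off the median are flagged. A raw-k mode
  (`outlier_on_log = FALSE`) exists for sensitivity analysis.
* **Coverage**: a chemical must have values in at least
  `ceiling(0.5 × n_sites)` site-experiments ("at least half of the
  ecosystems"); the ceiling reading keeps the boundary case 19/38.

All thresholds live in `preprocess_config()`.

## Grouping

The data-dependent ("optimized") grouping represents each chemical by its
vector of pairwise Pearson correlations of log10 k against every other
chemical (`pairwise_pearson()`): chemicals whose rate constants co-vary
across sites — i.e. respond to the same community functions — end up
close. Correlations use pairwise-complete sites; pairs sharing fewer than
5 sites, or with a zero-variance profile, are undefined and imputed with 0
in the feature vectors (no information ≈ no correlation). The diagonal 1
is kept so all vectors have equal length; a shared constant coordinate
does not affect between-chemical distances.

Clustering is agglomerative with Euclidean distance and Ward's
minimum-variance linkage, in the **Ward.D2** convention (squared distances
in the Lance–Williams update, merge heights on the distance scale: two
singletons a distance d apart merge at height d). The convention matters —
heights differ between Ward variants even when cuts agree — so it is fixed
and tested against an exhaustive ESS-recomputation oracle. `stats::hclust`
provides the implementation.

Group-specific benchmarking needs at least two chemicals per group, so
`cut_tree_min_size()` repairs a cut: while any cluster is under the
minimum size, the smallest one is absorbed into the cluster with the
smallest Ward linkage distance to it, reducing the effective group count
rather than re-cutting at a lower k — this preserves the requested
granularity as closely as possible. Descriptor-based groupings (MACCS,
btrules, btrules_prob) are cut plainly, without the repair: the minimum
size requirement belongs to the optimized grouping only, and an undersized
descriptor group simply cannot be benchmarked (which `run_gbm()` reports
as a configuration error rather than silently fixing). The number of
groups is always user-supplied; the package does not guess it.

## The synthetic generator

`simulate_rates()` draws
`log10 k[i, j] = mu_i + lambda_i * delta[g(i), j] + eps[i, j]`
with group-shared site effects `delta ~ N(0, sigma_group²)` and
independent noise `eps ~ N(0, sigma_noise²)`, missing cells completely at
random, and optional value-dependent censoring (`censor_below`) emulating
rate constants not significantly different from zero. One master seed
feeds per-component sub-streams, so switching one component (say,
outliers) off does not reshuffle the others.

Defaults are the study conditions the analysis targets: 8 groups × 8
chemicals, 38 site-experiments, `sigma_group = 0.3`, `sigma_noise = 0.1`
(spatiotemporal variability about 3–4× the measurement uncertainty, with a
total stddev near 0.3, i.e. a ~2-fold spread), 20 % missing, and chemical
means uniform on log10 k ∈ [−3, 1] (k from 0.001 to 10 d⁻¹, the realistic
span for degradable micropollutants). Loadings default to 1.

With unit loadings, a within-group benchmark removes `delta` entirely and
doubles the noise variance, giving the closed-form large-N expectation

    E(REM) ≈ sqrt(sigma_group² + sigma_noise²) − sqrt(2) · sigma_noise

(`expected_rem()`), 0.175 at the defaults, and negative when the group
effect is weak — benchmarking against an uncorrelated chemical adds noise.
Observed medians sit slightly below the closed form (≈0.16 at 20 %
missingness) because gap-filled residuals retain the site effect; the
validation tolerance of ±0.03 covers this.

What the generator does **not** emulate: heavy-tailed or skewed site
effects, chemical-specific loadings correlated with structure,
non-exchangeable site-experiments (true spatial/seasonal covariance), or
missingness that is informative beyond the simple censoring option.
Passing the recovery tests therefore shows the pipeline recovers the
variance structure it assumes, not that real data satisfy that structure.

## Validation and problem sizes

The test suite checks, among others:

* `rem()` against an independent brute-force transcription on 1000 random
  gappy matrices up to 5 × 5, to 1e−12;
* exact limits (perfect benchmark → REM = stddev; constant benchmark →
  REM = 0) on integer-valued inputs with dyadic offsets, where double
  arithmetic is exact;
* Ward merges against the exhaustive-variance oracle on 200 random
  instances of up to 8 items;
* study-scale recovery over 20 simulated seeds: Pearson-profile grouping
  attains adjusted Rand index ≥ 0.9 against the planted groups, optimized
  GBM's median REM lands within ±0.03 of the closed form, UBM does worse
  in ≥ 19 of 20 seeds, and the no-group-structure null yields median REM
  ≤ 0.01 (benchmarking must not manufacture variance reduction from
  noise).

These sizes keep the whole suite under a minute while leaving the
Monte-Carlo margins (3 standard errors where a mean is compared to an
expectation) meaningful.

## Known limitations

* The pH correction assumes only the neutral species degrades at the
  measured rate and treats multiprotic sites independently.
* Gap filling reuses the unbenchmarked residual, which biases `stddev'`
  toward `stddev` for gap-heavy chemicals; REM for such chemicals is
  conservative (pulled toward 0).
* Replicate stddevs are carried as metadata but not propagated into REM
  confidence intervals.
* Benchmark selection maximizes the median REM in-sample; with few
  chemicals per group the reported medians carry a selection optimism that
  the null-case test bounds but does not remove.
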
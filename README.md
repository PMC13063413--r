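# rembench

Chemical benchmarking of aquatic biodegradation rate constants.

First-order biodegradation rate constants (*k*, d⁻¹) measured for the same
chemical in different surface-water systems, or in the same system at
different times, commonly spread over several-fold ranges. That variability
is a central obstacle for persistence and exposure assessment: a half-life
measured in one river says little about the next one. Chemical benchmarking
treats a well-characterized reference chemical like an internal standard in
analytical chemistry: its measured rate constant at a site captures that
site's biodegradation capacity, which is then used to predict the
variability of other chemicals' rate constants. `rembench` is for
environmental chemists and exposure modellers who want to quantify how much
of the spatiotemporal variability in a rate-constant data set benchmarking
can actually remove, and whether the chemical groups that make it work can
be predicted from structure.

## The statistic

The benchmarking assumption is that the ratio of rate constants of chemical
*i* and benchmark BM is constant across sites *j*:

    k_i,j / k_BM,j = k_i,ref / k_BM,ref

On the log10 scale the benchmarked rate is log k′\_i,j = log k\_i,j − log
k\_BM,j. Efficacy for chemical *i* is the **REM** (reduction in
spatiotemporal variability):

    REM_i = stddev_i − stddev′_i

where stddev\_i is the sample standard deviation (N−1 denominator) of log
k\_i,j over the N sites with valid rate constants, and stddev′\_i is the
standard deviation of the benchmarked residuals. Where the benchmark is
invalid at a site, the chemical's own residual log k\_i,j − mean(log k\_i)
fills the missing benchmarked residual. REM > 0 means benchmarking reduced
the variability; on the log10 scale a stddev of 0.4 corresponds to a
2.5-fold spread (`fold_factor(0.4)`).

Two strategies are implemented:

* **UBM** (universal benchmarking): one benchmark for all chemicals. Each
  chemical is tried as benchmark against the rest; the one with the largest
  median REM wins (`run_ubm()`).
* **GBM** (group-specific benchmarking): chemicals are partitioned into
  groups and benchmarked only within their group (`run_gbm()`). Groups come
  either from the data itself — Ward clustering of each chemical's profile
  of pairwise Pearson correlations of log k (`pearson_grouping()`, the
  "optimized" grouping) — or from structure-based descriptors (166-bit
  MACCS fingerprints, biotransformation-rule triggers or probabilities,
  `descriptor_grouping()`).

Around the statistic the package provides the standard preprocessing steps
(normalization to the freely dissolved fraction, correction to a reference
pH via Henderson–Hasselbalch neutral fractions, per-chemical IQR outlier
removal, ecosystem-coverage filtering), TOC normalization as a non-chemical
baseline (`run_toc()`), and a synthetic generator of group-structured rate
constants with a closed-form expected REM for validation
(`simulate_rates()`, `expected_rem()`).

## Worked example

```r
library(rembench)

ds <- simulate_rates(sim_config(), seed = 42)   # 8 planted groups x 8 chemicals
ds$matrix
#> rate_matrix: 64 chemicals x 38 site-experiments (19.0% missing)

grouping <- pearson_grouping(ds$matrix, k_groups = 8)
grouping
#> group_assignment (pearson): 64 chemicals in 8 groups

run_gbm(ds$matrix, grouping)
#> GBM benchmarking: 56 chemicals benchmarked (0 skipped)
#>   median REM 0.1574 (fold factor 1.44); stddev reduced for 100% of chemicals
#>   8 groups; per-group median REM 0.118 to 0.231

run_ubm(ds$matrix)
#> UBM benchmarking: 63 chemicals benchmarked (0 skipped)
#>   median REM -0.0247 (fold factor 0.94); stddev reduced for 27% of chemicals

expected_rem(sim_config())
#> [1] 0.1748064
```

Group-specific benchmarking removes most of the group-shared site
variability: the median REM of 0.157 is close to the closed-form
expectation √(σ²\_group + σ²\_noise) − √2·σ\_noise = 0.175 (the shortfall
reflects gap-filled sites where the benchmark is missing), and every
chemical's stddev shrinks — a median 1.44-fold tightening of the spread.
One universal benchmark, in contrast, *increases* variability for most
chemicals (median REM < 0), because no single chemical tracks the site
effects of eight unrelated groups.

A command-line wrapper with `simulate`, `preprocess`, `cluster`, `ubm`,
`gbm` and `report` subcommands is installed at
`system.file("cli", "rembench", package = "rembench")`.

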
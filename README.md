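# spinesim

Monte Carlo power analysis for dendritic spine morphometry.

## The problem

Dendritic spines — the micron-scale protrusions that harbor excitatory
synapses — are extraordinarily diverse in shape. When two groups of
samples (cells or animals) are compared on a morphometric variable such
as spine length *L*, head width *H*, neck width *N* or projected
cross-sectional area *A*, that diversity translates into large
between-sample variation, and real treatment effects can be buried in
sampling noise while spurious ones surface. `spinesim` simulates such
experiments end to end so that an experimenter can ask, *before*
imaging: how many cells per group, and how many spines per cell, does a
given effect size require? Which variable and which statistical test
will see the change? And how badly can per-sample systematic effects
mislead a distribution-level test?

The core machinery:

* **A calibrated synthetic population.** Spines are drawn from a
  hierarchical archetype mixture (stubby / thin / mushroom /
  filopodium). Conditional on archetype, `L` and `N` are lognormal, `H =
  N·r` with a lognormal head/neck ratio `r`, and `A = κ·L·H·ε` with
  mean-one lognormal noise. Every marginal is therefore a lognormal
  mixture with closed-form moments, and the defaults are frozen by a
  deterministic moment-matching calibration to the heavy-tailed shapes
  reported for cultured hippocampal neurons: excess kurtosis ≈ 7.97 for
  length, ≈ 2.02 for head width, with a filopodia tail beyond 4–5 μm.
* **Change models.** Uniform linear growth of one variable (10/20/50%),
  head swelling, probabilistic elimination of long spines with
  count-preserving resampling, growth of small spines (area < 0.8 μm²),
  and a per-sample multiplicative Gaussian "systematic" factor with
  spread σ.
* **Statistical engines.** Pooled-variance Student t-test on per-sample
  means; exact two-tailed Mann–Whitney u-test (dynamic-programming
  enumeration of the rank-sum null; minimal attainable two-sided p is
  `2/C(n₁+n₂, n₁)`); two-sample Kolmogorov–Smirnov test on pooled
  spines; ratio-threshold spine classification (filopodium `L > 4`,
  stubby `L/N > 2`, mushroom `H/N ≥ 1.3`, else thin) with per-sample
  subclass-fraction comparisons.
* **The simulator.** False-negative / false-positive rate estimation
  with Wilson intervals (2000 / 10000 runs by default), minimal-sample
  search, power-table grids and false-positive sweeps over σ, all
  bit-reproducible from one master seed.

## A worked example

```r
library(spinesim)

pop <- generate_population(default_spine_model(), n = 2e5, seed = 1)
excess_kurtosis(pop$length)
#> [1] 8.083666

# How many cells per group to detect 20% head-width growth
# (60 spines/cell, t-test on per-cell means, alpha = 0.01, FNR <= 5%)?
cfg <- experiment_config(
  pop, n = 2, m = 60, variable = "head_width",
  change = change_model("linear_growth", variable = "head_width",
                        factor = 1.2),
  test = test_spec("t_test", alpha = 0.01))
find_min_samples(cfg, max_fnr = 0.05, runs = 2000, seed = 1)$n
#> [1] 5

# The same effect through mushroom-fraction counting needs ~3x more cells
cfg$test <- test_spec("subclass_fraction", class = "mushroom", alpha = 0.01)
find_min_samples(cfg, max_fnr = 0.05, runs = 2000, seed = 1)$n
#> [1] 16

# K-S false positives under per-sample systematic factors (n = 4 cells)
fpr_sigma_sweep(pop, sigmas = c(0, 0.15), n = 4, m = 60,
                alpha = 0.01, runs = 2000, seed = 1)[, 1:4]
#>   sigma  m   rate  ci_low
#> 1  0.00 60 0.0140 0.0097
#> 2  0.15 60 0.1635 0.1479
```

Five cells per group suffice for a direct 20% head-width comparison,
but counting mushroom-class spines needs sixteen; and a ±15%
per-sample systematic factor inflates the nominal 1% K-S false positive
rate more than tenfold — the two cautionary results the simulator is built
to quantify. A command-line wrapper with the same functionality ships
in `inst/scripts/spinesim.R` (subcommands `generate-population`,
`simulate`, `power-table`, `fpr-sweep`, `classify`).

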
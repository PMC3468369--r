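---
title: "Power analysis for dendritic spine morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power analysis for dendritic spine morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinesim)
```

## What the simulator models

A morphometric comparison of dendritic spines has a simple skeleton:
two groups — control and treatment — of $n$ samples (cells or animals),
each contributing $m$ measured spines; a morphometric variable (spine
length $L$, head width $H$, neck width $N$, cross-sectional area $A$,
in μm or μm²); and a statistical test applied either to per-sample
means, to the pooled spine-level distributions, or to per-sample
fractions of spines in a morphological subclass. `spinesim` makes every
element of that skeleton explicit and simulates the whole experiment
many times, so Type I and Type II error rates become measurable
quantities rather than hopes.

In a single simulation run, both groups are assembled by sampling
spines *with replacement* from a base population table; a change model
is applied to the treatment group; the configured test is run; and the
rejection outcome is recorded. Rates are estimated over an ensemble of
runs — 2000 by default for false negative rates, 10000 for false
positive rates — and reported with Wilson 95% intervals. Sampling with
replacement keeps group construction well defined for any $n \cdot m$
(the replacement policy is not dictated by the experimental situation
itself, and matches bootstrap practice).

## The synthetic population and its calibration

Real spine morphometry databases are rarely shareable, so the package
ships a generative stand-in. It is explicitly *synthetic*: a
hierarchical archetype mixture whose parameters are frozen by matching
the distribution-shape facts that characterise cultured hippocampal
neurons rather than by fitting any proprietary data table.

Each spine first draws an archetype — stubby, thin, mushroom or
filopodium, with default weights fixed by calibration (roughly
0.25/0.40/0.25/0.10 before it). Conditional on the archetype:

$$L \sim \mathrm{LN}(\mu_L, \sigma_L), \quad
  N \sim \mathrm{LN}(\mu_N, \sigma_N), \quad
  r = H/N \sim \mathrm{LN}(\mu_r, \sigma_r), \quad
  A = \kappa\, L H \varepsilon,$$

with $\varepsilon$ a mean-one lognormal noise factor
($\sigma_\varepsilon = 0.25$) and $\kappa = 0.7$. The product
construction induces realistic positive correlation among $L$, $H$ and
$A$ and a heavy area tail, while keeping every marginal a
four-component lognormal mixture — so means, variances and kurtoses
are available in closed form (`model_moments()`), and calibration needs
no Monte Carlo at all.

Parameter choices worth stating explicitly:

* **Head/neck ratio modes** sit on either side of the mushroom/thin
  classification boundary of 1.3: thin and stubby spines near
  $r \approx 1$, mushroom near $r \approx 1.6$, with log-scale spreads
  of 0.22–0.25. Neck widths are measured near the resolution limit of
  confocal imaging, so wide ratio spread is the realistic regime; it
  also means subclass membership is genuinely noisy, as it is in
  practice.
* **Archetype head-width means** are mildly separated (0.30–0.60 μm),
  giving the near-unimodal head-width marginal actually observed.
* **Filopodia** have a length scale of 5 μm, so the archetype weight is
  (to a good approximation) the fraction of spines beyond 4 μm, and the
  length distribution carries a genuine tail beyond 5 μm.

`calibrate_spine_model()` then adjusts exactly three knobs — the
filopodium weight, a common scale on the length spreads, and the shared
neck spread — by a coarse grid search plus box-constrained
quasi-Newton refinement on the closed-form moments, until the
population excess kurtosis of length and head width hit their targets
(7.97 and 2.02; tolerance ±10%). The result is frozen in
`inst/extdata/default_model.json` and shipped; `default_spine_model()`
loads it. The area kurtosis is deliberately *not* a calibration target:
the heavy area tail (excess kurtosis ≈ 10 for the frozen model) is a
structural consequence of the $\kappa L H \varepsilon$ coupling.

```{r moments}
round(model_moments(default_spine_model()), 3)
```

Kurtosis here is always the bias-uncorrected fourth standardised
central moment minus 3 (`excess_kurtosis()`): zero for Gaussian data,
−1.2 for uniform, large and positive for the filopodia-tailed length
distribution.

What the generator does **not** emulate: within-cell correlation of
spines (spines of one sample are exchangeable draws), measurement error
of the imaging pipeline, dendrite-rank or developmental gradients, and
any correlation structure beyond the one induced by the hierarchical
construction (the real joint distribution of $L, H, N, A$ is
unreported). Passing simulations therefore bound what *sampling
diversity alone* does to an experiment — real experiments have further
variance sources, so real sample-size requirements are lower bounds.

## Change models

* `linear_growth` multiplies one variable of every treatment spine by a
  factor (10/20/50% growth are the canonical magnitudes);
  `head_swelling` is the same restricted to head width.
* `filopodia_elimination` removes each spine with $L > 2$ μm with
  probability 0.5 and replaces it with a fresh population draw passed
  through the same filter, keeping $m$ fixed. The surviving fraction of
  long spines follows the renewal form $q(1-p)/(1-pq)$, which the test
  suite checks against direct stochastic enumeration. Replacements from
  the whole database (refiltered) are the default; drawing only from
  the short-spine pool is available as a switch
  (`replacement_from = "below_threshold"`), since the underlying
  biology (filopodia maturing versus vanishing) does not dictate the
  choice.
* `small_spine_growth` multiplies the area of spines with pre-change
  $A < 0.8$ μm² by 1.5; membership is decided before modification.
* `systematic_perturbation` draws one factor per sample from
  $\mathcal N(1, \sigma^2)$ — redrawn until positive, which preserves
  the unit mean to high accuracy for $\sigma \le 0.2$ — and multiplies
  the chosen variable of all $m$ spines by it. $\sigma$ is read as the
  *relative spread* of the factor (a 5–15% sweep is the interesting
  regime), not a variance in squared units.

## Statistical engines and numerical choices

**Student t-test.** The classic pooled-variance form (not Welch),
computed in closed form, with fixed conventions for degenerate input:
identical constant groups give $p = 1$; distinct constant groups give
the smallest representable positive $p$. Equality with
`t.test(var.equal = TRUE)` on regular input is asserted in the tests.

**Exact Mann–Whitney u-test.** Software packages disagree on u-test
p-values because of undocumented approximations, so the package
enumerates the exact rank-sum null by dynamic programming whenever
$\min(n_1,n_2) \le 15$, $n_1+n_2 \le 40$ and the data are tie-free
(subset counts stay below $2^{53}$, so doubles are exact). The
two-sided p is $2\min(P(W \le w), P(W \ge w))$ capped at 1. The
smallest attainable p is $2/\binom{n_1+n_2}{n_1}$ — for equal groups at
$\alpha = 0.001$ this first drops below the level at $n = 7$, so
smaller experiments *cannot* yield a positive u-test outcome at that
level. Beyond the exact regime, or with ties (midranks), a
continuity-corrected normal approximation with tie correction is used.
Because the exact test is discrete, its null size is $\le \alpha$
rather than $= \alpha$; the test suite compares its Monte Carlo
rejection rate against the exact size computed from the same
enumeration, not against $\alpha$.

**Kolmogorov–Smirnov.** Supremum distance over the pooled empirical
CDFs (tie blocks contribute only their final step), with the exact
small-sample distribution below an effective size
$n_1 n_2/(n_1+n_2) = 35$ and the asymptotic Kolmogorov series at or
above it. The switchover is a fixed constant for cross-machine
reproducibility.

**Classification.** Filopodium ($L > 4$ μm), else stubby
($L/N > 2$), else mushroom ($H/N \ge 1.3$) or thin — applied in that
order, strict inequalities for the first two rules, boundary
$H/N = 1.3$ assigned to mushroom so the rule is total. The printed
stubby criterion $L/N > 2$ is biologically atypical (stubby spines are
conventionally *short* relative to their neck); it is implemented as
conventionally printed, with every threshold configurable, rather than
silently "fixed". The binary large/small split uses the *median area of
the base population computed at experiment setup*, not a hard-coded
value — the conventional 0.65 μm² figure is a property of one
particular database.

**Seeds.** Every estimator takes one master seed; run $r$ of grid cell
$c$ uses the derived stream seed
$(48271 s + 100003 c + r) \bmod (2^{31}-1)$. Results are
bit-reproducible and independent of cell evaluation order, and
operations leave the caller's RNG state untouched
(`withr::with_seed`).

**Minimal-n search.** `find_min_samples()` scans $n$ upward and
accepts the first $n$ whose false-negative point estimate at 2000 runs
is ≤ 5% (the run budget matches the rate being resolved). An exact
early-stop abandons a candidate $n$ as soon as its failure count can no
longer meet the target, which leaves the decision unchanged but makes
grid scans cheap. A stricter mode (`mode = "wilson"`, upper Wilson
bound ≤ 5%) is available since the point-estimate convention is a
choice, not a law.

## Study conditions used by the shipped checks

The acceptance-style checks in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` run at these problem sizes, chosen to resolve
the rates in question within a few minutes of CPU time:

* Null calibration: $n = 8$, $m = 60$, head width, $10^4$ runs, at
  $\alpha = 0.01$ and 0.001.
* Generator calibration: $10^6$ fresh draws; ±10% on the two kurtosis
  targets; a $10^6$-draw Gaussian control stays within ±0.05 of zero.
* Subpopulation dichotomy (2000 runs, $\alpha=0.01$, $m=60$):
  filopodia elimination is examined at $n = 12$ — on this population
  the canonical $n = 30$ leaves both tests with rates
  indistinguishable from zero, so the comparison is made where rates
  are measurable — and small-spine growth at $n = 5$. The mean-based
  t-test beats the K-S test under elimination (the effect lives in the
  tail of $L$ and shifts the mean), while K-S beats the t-test under
  small-spine growth (many small shifts reshape the distribution but
  the mean change drowns in the heavy area tail) — margins are required
  to exceed two pooled binomial standard errors.
* Minimal-n structure (500 runs/cell on a six-cell subgrid): head-width
  ≤ length ≤ area within a setting; non-increasing in magnitude and in
  $m$.
* K-S inflation: $n=4$, $m \in \{15, 60\}$,
  $\sigma \in \{0, 0.05, 0.10, 0.15\}$, 3000 runs per point,
  $\alpha = 0.01$.
* Subclass-fraction inefficiency: head swelling ×1.2 at $m = 60$,
  $\alpha = 0.01$, 500 runs per candidate $n$, mushroom-fraction versus
  direct head-width minimal $n$.

## Design decisions in open territory

* **Fraction tests use the Student t on per-sample fractions** — the
  natural "datum per cell" reading of subclass comparisons, matching
  the convention used for means.
* **Binary-fraction inefficiency is summarised by the largest
  admissible fold.** The false-negative inflation of the large/small
  area split relative to the direct area test depends strongly on where
  in the admissible window (direct FNR between 1% and 50%) a setting
  sits: on the frozen population it is ≈1.1–1.5 in the middle of the
  window and reaches ≈2–2.5 near its informative low-FNR edge, the
  region where experiments are actually designed to operate.
  `binary_fraction_folds()` therefore scans the settings grid
  (magnitude × $m$ × admissible $n$, both tests paired on identical
  simulated groups) and reports the largest fold — the analogue of the
  upper end of the "2–100× depending on setting" phenomenon, which on
  this synthetic population is milder than on real data.
* **EM for the length mixture** (`fit_length_mixture()`) is a plain
  univariate expectation-maximisation with quantile initialisation, a
  relative-scale floor on component spreads, components reported sorted
  by mean, and the log-likelihood trace exposed; non-convergence raises
  a condition carrying the best-so-far fit. The test suite cross-checks
  it against `mclust` on shared data.
* **Three Gaussian components for spine length** are a parametrisation,
  not a claim that three biological classes exist; on the frozen
  population the fitted top component lands in the filopodia range, as
  it should.

## Limitations

* The synthetic population reproduces marginal shapes and a plausible
  correlation structure, not any real database; quantitative minimal-n
  values transfer to real experiments only as orders of magnitude, and
  the package deliberately reports the *structure* of the power table
  (orderings and monotonicities) as its testable claim.
* Per-sample means of 15–60 heavy-tailed spines are not Gaussian;
  the t-test's observed null calibration is an empirical finding at
  these sizes, not a theorem.
* Spine dynamics (motility, live-imaging designs) and measurement error
  are out of scope; so is any multiple-testing correction across grid
  cells.
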
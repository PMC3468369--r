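Package: spinesim
Title: Monte Carlo Power Analysis for Dendritic Spine Morphometry
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation framework for planning and auditing quantitative
    comparisons of dendritic spine morphology. Provides a calibrated
    synthetic spine population (length, head-width, neck-width and
    cross-sectional area drawn from a hierarchical lognormal archetype
    mixture), treatment-effect models (uniform linear growth, filopodia
    elimination, growth of small spines, head swelling, per-sample
    systematic perturbation), the statistical engines used in such studies
    (pooled-variance Student t-test on per-sample means, exact two-tailed
    Mann-Whitney u-test, two-sample Kolmogorov-Smirnov test, spine
    subclass-fraction comparisons), and Monte Carlo estimators of false
    negative and false positive rates together with minimal sample-size
    search over experiment grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
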
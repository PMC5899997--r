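Package: navclamp
Title: Voltage-Clamp Simulation and Biophysical Analysis of NaV1.4 Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates whole-cell skeletal-muscle sodium channel (NaV1.4)
    currents under standard activation, steady-state fast-inactivation and
    recovery-from-inactivation voltage-clamp protocols, and re-measures the
    seven canonical gating parameters (peak current density, activation and
    fast-inactivation Boltzmann midpoints and slope factors, and the time
    constants of open-state inactivation and of recovery) from the simulated
    sweeps by Boltzmann and exponential curve fitting.  Provides variant
    versus wild-type hypothesis testing (Kruskal-Wallis with Dunn's control
    comparisons, or Welch ANOVA with Games-Howell), a fixed Bonferroni
    family threshold, gain/loss-of-function classification of channel
    variants, and one-tailed Fisher exact rare-variant carrier and
    variant-level burden tests for case-control cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'gating-model.R'
    'trace-analysis.R'
    'cell-analysis.R'
    'variant-stats.R'
    'classify.R'
    'burden.R'
    'protocols.R'
    'cohort.R'
    'io.R'
    'navclamp-package.R'
    'table2-data.R'
    'pipeline.R'
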
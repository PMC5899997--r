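---
title: "Simulating and measuring NaV1.4 gating: models, parameters and design choices"
author: "navclamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and measuring NaV1.4 gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navclamp)
```

## What this package models

NaV1.4 is the voltage-gated sodium channel of skeletal muscle.  Its function
in a whole-cell voltage-clamp experiment is conventionally summarised by
seven parameters: the peak current density at a 0 mV test step (pA/pF), the
midpoint and slope factor of the activation conductance-voltage curve, the
midpoint and slope factor of the steady-state fast-inactivation
(availability) curve, the time constant of open-state fast inactivation at
0 mV, and the time constant of recovery from fast inactivation at -80 mV.
Rare missense variants shift these parameters in either a gain-of-function
direction (impaired inactivation: depolarised availability midpoint, slower
inactivation onset, faster recovery) or a loss-of-function direction
(reduced current density, enhanced inactivation).

`navclamp` re-creates that measurement chain end to end: a Hodgkin-Huxley
style simulator produces whole-cell current sweeps for cohorts of virtual
cells under the three standard protocols; the analysis layer re-measures the
seven parameters from those sweeps by the conventional curve fits; the
statistics layer compares each variant cohort against wild type under a
fixed Bonferroni family threshold and classifies variants; and the burden
layer runs the one-tailed Fisher exact carrier and variant-level tests for a
rare-variant case-control design (278 cases against 729 controls, with
variants kept when novel or below a population allele frequency of
0.00005).

## The gating model

Whole-cell current is

$$I(t) = g_{max}\, C\, m(t)^{p}\, h(t)\, (V - E_{rev}),$$

with $p = 3$, $C$ the cell capacitance, and both gates relaxing
exponentially at fixed voltage, $\dot m = (m_\infty - m)/\tau_m$,
$\dot h = (h_\infty - h)/\tau_h$.  Because clamp protocols are piecewise
constant in voltage, the per-epoch solution is the exact exponential
relaxation; the simulator evaluates it on the sample grid rather than
integrating numerically, so there is no discretisation error in the state.
It still refuses a sampling interval coarser than one fifth of the fastest
time constant, because the *measurement* layer (peak detection, decay
fitting) needs the kinetics resolved.

Three choices deserve explanation:

* **The activation steady state is the cube root of the target Boltzmann.**
  The quantity the experiment reports is the conductance-voltage curve
  $G(V) \propto m_\infty(V)^3$ fitted with a single Boltzmann.  Had we made
  $m_\infty$ itself that Boltzmann, the measured midpoint would sit several
  millivolts depolarised of the stored parameter (cubing shifts the
  half-maximum by $k\ln(2^{1/3}/(2^{1/3}-1)) \approx 8\,\mathrm{mV}$ for a
  6.4 mV slope).  Defining $m_\infty = B(V)^{1/3}$, with $B$ the stored
  activation Boltzmann, makes the simulated ground truth directly the
  quantity the fit estimates, which is what parameter-recovery testing
  requires.

* **$\tau_h(V)$ interpolates log-linearly between its two measured
  anchors** -- the onset time constant at 0 mV and the recovery time
  constant at -80 mV -- and is clamped outside $[-80, 0]$ mV.  These are
  the only two voltages at which the experiment constrains the kinetics, and
  log-linear interpolation is the simplest positive form through both.

* **$\tau_m(V)$ is proportional to $\tau_h(V)$** (0.03 ms at 0 mV).  The
  peak of $m(t)^3 h(t)$ after a step depends only on the ratio
  $\tau_m/\tau_h$ (up to the small equilibrium occupancies), so proportional
  kinetics make the peak-current attenuation the *same at every test
  voltage*.  The measured conductance-voltage curve is then an undistorted
  scaled copy of the target Boltzmann.  We initially tried the more
  biophysical bell-shaped $\tau_m(V)$; the voltage-dependent attenuation it
  produces biases the fitted activation midpoint by 1-3 mV, which is larger
  than the shifts of interest for several variants, and it was dropped.  The
  cost of this choice is a fast activation time constant, which forces the
  default sampling interval down to 0.005 ms (200 kHz); sweeps are short, so
  this stays cheap.

Other defaults: reversal potential +65 mV (physiological sodium reversal in
typical recording solutions); additive white Gaussian current noise of
10 pA, with no capacitive-transient or leak component (published traces are
shown subtracted); series resistance is modelled only through its voltage
error $|I_{peak}| R_s$ for quality control, not as a command distortion,
which keeps the simulator linear in conductance while reproducing exactly
the QC rule the measurement chain applies.  Capacitance is drawn at
12 +/- 3 pF and series resistance at 2 +/- 0.5 MOhm, typical small-cell
whole-cell values.

## The measurement chain

* **Peaks** are signed extrema after baseline subtraction, on a trace
  smoothed with a five-sample running mean.  Without smoothing, the extremum
  of thousands of noisy samples is biased outward by roughly
  $\sigma\sqrt{2\ln n} \approx 40$ pA, which distorts small tail currents
  and short-interval recovery ratios; light filtering (as acquisition
  hardware applies anyway) reduces the bias below the per-cell variability.
* **Reversal potential** is extrapolated from a linear fit to the I-V limb
  at or above +20 mV (at least three points), falling back to the
  configured +65 mV when the limb is unusable.  Conductance points within
  5 mV of the reversal are excluded.
* **Boltzmann fits** are plain nonlinear least squares
  ($y = B + (A-B)/(1+\exp(\pm(V_{1/2}-V)/k))$), initialised from the data
  (asymptotes from the extreme-voltage means, midpoint from the
  half-crossing, slope 6 mV).  The availability curve per cell is the peak
  tail current in the first 5 ms at -10 mV after each 150 ms pre-pulse;
  per-cell curves are normalised to the fitted asymptotes before averaging.
* **Onset of inactivation** is fitted with a double exponential from the
  peak of the 0 mV sweep (a 0.06 ms dead time skips activation-gate
  settling; the window spans 8 ms).  On decays that are effectively
  single-exponential a free double-exponential is ill-posed -- the optimiser
  splits one component into two near-identical time constants with huge
  opposite amplitudes -- so the implementation falls back to the
  single-exponential fit whenever the second component fails to reduce the
  residual sum of squares by at least 5% or the optimisation does not
  converge, and drops components carrying under 5% of the amplitude.  The
  reported time constant is the fastest surviving component; its amplitude
  share is recorded, with a note when it falls below 0.95.
* **Recovery** is the P2/P1 peak ratio against the interval at -80 mV,
  fitted as $1 - a e^{-\Delta t/\tau}$ with the asymptote fixed at 1 and
  amplitude free (the experiment fits "a single exponential" without
  stating the asymptote; fixing it at full recovery is the physically
  constrained reading).  The shipped interval ladder is
  0, 1, 2, 5, 10, 20 ms plus 30 and 50 ms so the asymptote is sampled.
* **Quality control** is two nested tiers: cells with peak current above
  0.1 nA count for the density column; only cells above 0.5 nA with a
  series-resistance error below 5 mV enter the analysis of the remaining
  parameters.

Round-trip accuracy on noiseless, variability-free cells is better than
0.2 mV on both midpoints and 2% on both time constants; these bounds are
asserted in the test suite.

## Cohorts, variability and the reference table

The reference table (`nav14ReferenceCohorts()`) stores mean, SE and N for
the wild-type channel, six case-cohort variants and eight control-cohort
variants.  Per-cell spreads are taken as $SE\sqrt{N}$, so that a simulated
cohort at the tabulated N reproduces the tabulated SE.  Two wild-type SEs
print as zero at the table's precision; they are replaced by half of one
least-significant printed digit (0.005 ms and 0.05 mV), the least
informative value consistent with the rounding, since a literal zero would
make those draws degenerate.  Voltages are drawn normal; positive-magnitude
quantities (slopes, time constants, densities) log-normal with matching
mean and coefficient of variation, which keeps them physical without
truncation.  Draws that still violate the physical bounds (for example a
time constant too fast to sample) are redrawn with a bound and counted.

Each cell's maximal conductance is calibrated by a noiseless probe sweep so
that its drawn target peak density is what a noiseless measurement would
return; with the cell-size distribution above, the 0.1/0.5 nA QC cuts then
thin the tiers at roughly the rates implied by the differing per-parameter
N in the reference table.

Trace-level simulation costs about 0.2-0.3 s per cell, so the full 15-cohort
design (~350 cells) is simulated trace-level only where the traces matter.
For purely statistical properties (significance patterns across many
replicates, family-wise error under the null) the package draws per-cell
*fitted-parameter* tables directly (`simulateParameterTable()`), using the
same draw machinery and spreads; the round-trip tests justify treating the
trace stage as unbiased.  Problem sizes used by the shipped acceptance
script: trace-level replicates of the wild-type (4), Val1442Met (8) and
Arg1463Ser (8) cohorts at the tabulated N, averaged -- the small variant
cohorts dominate the shift estimates' sampling error, so they get the
extra replicates; 20 parameter-level replicates of all
15 cohorts for the significance pattern; 1000 parameter-level replicates
for the null family-wise error rate.

What the generator does *not* emulate: capacitive transients, leak and
seal instability, series-resistance voltage distortion, rundown over the
recording, correlated (1/f or line) noise, and any within-cell correlation
between parameters.  Passing tests therefore demonstrate that the analysis
chain is calibrated and unbiased for data satisfying the model's
assumptions, not that it is robust to every artefact of real recordings.

## Statistics

Each variant is compared with wild type on the seven parameters, with
significance declared at the fixed threshold $\alpha/(14 \times 7) =
0.00051$ -- a threshold on raw p-values, not a p-value multiplication,
matching how the original analysis states it.  Two post-hoc schemes are
implemented, both computed after a single pooling across all cohorts:

* `kw_dunn`: Kruskal-Wallis family with Dunn's control comparisons on the
  pooled ranks, tie-corrected, two-sided normal p-values;
* `anova_games_howell`: Welch-type contrasts with Welch-Satterthwaite
  degrees of freedom, referred to the studentized-range distribution with
  $k$ groups at $q = |t|\sqrt 2$ (with two groups this is exactly the
  Welch t-test).

The source analysis used both families without stating which parameters
used which.  The package default is `kw_dunn`: on cohorts simulated from
the reference table at the tabulated N it reproduces the published
significance calls cell-for-cell more faithfully (about 94.5 of 98 cells on
average) than Games-Howell (about 92.7), mainly because the
studentized-range reference with 15 groups is very conservative deep in the
tail where the 0.00051 threshold lives.  Both schemes remain selectable in
every entry point.  Two-sided tests are used throughout (the source does
not state sidedness); the tested onset time constant is the 0 mV value,
the one the reference table tabulates.

No choice of scheme reproduces the published significance pattern exactly
in most replicates, and the package does not pretend otherwise.  The
printed summary statistics themselves are incompatible with two of the
published calls: the starred activation slope factor of Ser682Trp
(7.2 +/- 0.2 against 6.4 +/- 0.1) implies a Welch p around 0.0015, above
the threshold, while the unstarred activation midpoint of Arg1463Ser
(-17.4 +/- 0.5 against -19.5 +/- 0.2) implies a p below it.  Simulations
faithful to the summary table therefore miss the first star and add the
second in a substantial fraction of replicates; the original calls
presumably reflect features of the unpublished raw distributions.  The
acceptance suite asserts the strict pattern-match criterion anyway and
reports its failure honestly, alongside the per-cell agreement rate.

Classification applies the field's reading of the parameter shifts in
precedence order: any significant inactivation-impairing change
(depolarised availability midpoint, faster recovery, slower onset,
increased availability slope) makes a variant gain-of-function; otherwise a
significant density reduction, hyperpolarised availability midpoint or
slower recovery makes it loss-of-function; otherwise it is wild-type like.
When both kinds of evidence coexist (reduced density together with impaired
inactivation) the gain-of-function reading wins and the conflict is kept in
the evidence table.  Significant shifts matching neither list -- an
isolated activation-slope change, a density increase, a faster onset --
contribute no evidence; this is deliberate, since neither reading of
channel function follows from them alone.

## Burden tests

Carrier-level tests count one carrier per qualifying variant record (no
individual in the shipped table carries two qualifying variants; multiple
qualifying variants in one carrier would be collapsed).  The one-tailed
Fisher exact p is the hypergeometric upper tail $P(X \ge a)$ with
enrichment towards cases.  The variant-level test rows are distinct
variants; its control denominator includes the intronic control variant
(nine control variants), the only reading that reproduces the published
variant-level result, verified against the enumeration oracle.  The
"sensitivity" selector treats that intronic variant as deleterious at the
carrier level.  Display rounding is two significant figures; full precision
is kept internally.

## Reproducibility

One global seed drives everything through a named-stream splitter
(`seed x stream-name x index` hashed into a 32-bit seed), so adding a
cohort or re-ordering stages never perturbs another cohort's draws, and
identical configuration plus seed gives byte-identical output files.  The
pipeline writes `cells.tsv`, `variants_summary.tsv`, `comparisons.tsv`,
`classification.tsv`, `burden.tsv` and a `manifest.json` with the
configuration hash and seed.  Trace data round-trip through a plain-text
dialect: one TSV sweep table per protocol and cell plus a JSON sidecar
carrying the cell metadata and full protocol definitions, so externally
exported sweeps in the same layout can be analysed with the identical
chain.

## Known limitations

* A two-gate Hodgkin-Huxley scheme cannot express slow inactivation,
  state-dependent drug block or the coupled activation-inactivation
  kinetics of Markov models; it is the minimal model reproducing the seven
  measured quantities, no more.
* Recovery at short intervals carries a small (<2%) upward bias from
  activation-gate carry-over between the paired pulses; it is within the
  stated round-trip tolerance but visible in the 1 ms point.
* The statistical layer treats cells as independent; transfection batches
  and recording days are not modelled.
* All population-genetics steps upstream of the variant table (alignment,
  calling, ancestry matching) are out of scope; the table is an input.
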
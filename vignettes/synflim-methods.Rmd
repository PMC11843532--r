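---
title: "Lifetime, phasor and kinetics methods in synflim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifetime, phasor and kinetics methods in synflim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synflim)
```

# The measurement this package models

Molecular-rotor dyes such as thioflavin T report on amyloid aggregation
through two channels. Their bulk fluorescence *intensity* switches on only
when mature fibrils appear, producing the familiar sigmoid with a lag phase
and a half-rise time t50. Their fluorescence *lifetime*, measured by
time-correlated single-photon counting (TCSPC), lengthens as soon as the
rotor's intramolecular rotation is hindered — which happens already in
oligomeric species — so the amplitude-weighted mean lifetime rises well
before the intensity does. `synflim` implements the full analysis chain for
such experiments (decay fitting, mean lifetime, phasor plots, reference-set
classification, channel-delay kinetics) together with a synthetic-data
generator that emulates whole aggregation experiments, so every step can be
tested end to end against known ground truth.

# Decay model and simulation

A fluorescence decay is modelled as a sum of exponentials,
$I(t) = \sum_{i=1}^{n} \alpha_i e^{-t/\tau_i}$ with $n \le 3$, amplitudes
$\alpha_i \ge 0$ and lifetimes $\tau_i > 0$ (ns). Under pulsed excitation at
repetition rate $f$ (default 80 MHz, period $T = 12.5$ ns) a molecule
excited by one pulse may still be emitting when the next arrives. Summing
the tails of all preceding pulses is exact for exponentials,

$$\sum_{m \ge 0} e^{-(t + mT)/\tau} = \frac{e^{-t/\tau}}{1 - e^{-T/\tau}},$$

so `expected_curve()` evaluates this steady-state periodic decay at the bin
centers and convolves it *circularly* with the instrument response function
(IRF). Circular convolution over one period is the correct operation for a
periodic steady state, and it makes the treatment of incomplete decay exact
rather than truncated — relevant here because rotor lifetimes up to ~2 ns
leave a percent-level inter-pulse carryover at 80 MHz.

Choices worth knowing:

* **Time axis.** Bin centers, default 4096 bins over one period (the
  pipeline default is 1024 bins, which keeps per-timepoint fits fast while
  the discretization error stays far below the photon noise at the budgets
  used). The bin count is configurable everywhere.
* **IRF.** A normalized discrete density on the same bins. A Gaussian IRF
  (default FWHM 0.2 ns, centered at 1 ns) stands in for a measured scatter
  IRF; measured IRFs can be imported through the decay CSV format with
  `# kind=irf`.
* **Noise.** Photon counts are Poisson draws around the expected curve
  scaled to the requested photon budget. Every stochastic operation takes an
  explicit seed; a run-level seed is fanned out deterministically by
  `subseed(seed, index) = (seed + 1000003·index) mod (2^31 − 1)`.
* **Pixels.** FLIM images are reduced by summing pixel decays bin-wise
  (`sum_pixel_decays()`), pooling photons into one high-count decay per
  image.

# Fitting and the amplitude-weighted mean lifetime

`fit_decay()` performs weighted least squares of the reconvolved model plus
a constant background against the measured counts, with Neyman weights
$1/\max(c_k, 1)$ — the standard TCSPC chi-square variant. The fit range runs
from the IRF peak bin to the end of the window (configurable), which avoids
rising-edge sensitivity. Optimization uses Levenberg–Marquardt with box
constraints ($\alpha_i \ge 0$, $\tau_i > 0$, background $\ge 0$); without a
user-supplied start the fitter launches from a grid of lifetime combinations
spanning 0.05–5 ns (5–6 starts per model order) and keeps the best
chi-square. Fitted components closer than a lifetime ratio of 1.2 are merged
(amplitude-summed, amplitude-weighted lifetime) before reporting, since such
pairs are not separable in practice.

`select_model()` picks the model order: the smallest $n$ with reduced
chi-square below 1.3; failing that, the smallest $n$ beyond which one more
component improves the fit by less than 5%; failing that, the maximum order
(3). Each order's search additionally starts from the best lower-order fit
padded with a vanishing component, which guarantees the reduced chi-square
is non-increasing in $n$ up to optimizer tolerance.

The summary statistic is the amplitude-weighted mean lifetime

$$\tau_m = \frac{\sum_i \alpha_i \tau_i}{\sum_i \alpha_i},$$

invariant under amplitude rescaling and always between the shortest and
longest component lifetime.

# Phasor analysis

The first-harmonic phasor of a decay histogram is

$$g = \frac{\sum_k I(t_k)\cos(\omega t_k)}{\sum_k I(t_k)}, \qquad
  s = \frac{\sum_k I(t_k)\sin(\omega t_k)}{\sum_k I(t_k)},$$

with $\omega = 2\pi f$ the angular repetition frequency (0.5027 rad/ns at
80 MHz). Sums are rectangle-rule sums over bin centers — the histogram *is*
counts per bin — with error $O(\text{bin width})$, negligible at default
binning. Single-lifetime decays have the closed form
$g = 1/(1+(\omega\tau)^2)$, $s = \omega\tau/(1+(\omega\tau)^2)$, which
satisfies $g^2 + s^2 = g$: all monoexponential decays lie on the *universal
circle* of center (1/2, 0) and radius 1/2, and mixtures lie strictly inside
it, on the line segment joining their components' phasors with
intensity weights $\alpha_i\tau_i$. This linearity is what makes the phasor
plane a species-mixing diagram.

Uncertainties are parametric bootstrap: replicate histograms are drawn
Poisson around the observed counts and the error bars are **twice the SD**
of the replicate phasors (50 replicates by default), emulating the scatter
of technical repeats. No IRF correction is applied by default; an optional
single-reference calibration (complex division by a known monoexponential
reference phasor) is available and flagged in metadata. Only the first
harmonic is computed. Note that the IRF delay *rotates* measured phasors
relative to their ideal positions; because trajectories and reference sets
are measured with the same IRF, all comparisons happen consistently in the
measured space, and rotation is an isometry so overlap distances are
preserved.

# Region classification

Classification operationalizes an overlap rule between a time-ordered
aggregation trajectory and titration reference sets (preformed fibrils;
stabilized oligomers as a Type-B surrogate):

* two phasor points *overlap* when their 2-sigma error bars intersect in
  **both** the g and s directions;
* the trajectory is cut into contiguous sliding-window segments (default
  window 5 points, stride = window, remainder merged into the last
  segment);
* a segment is **fibrillar** if at least 60% of its points overlap at least
  one fibril reference point; otherwise **Type-B oligomeric** under the same
  rule against the stabilized-oligomer reference; otherwise **Type-A
  oligomeric** if it clearly deviates from both references (both overlap
  fractions at most 40%); otherwise **unassigned**;
* if a segment qualifies for both references the fibrillar label wins —
  stabilized oligomers partially overlap fibril phasors, so ties are
  expected — and both fractions plus a tie flag are always reported.

The window, the 60% threshold and the 40% deviation cutoff are parameters:
the underlying experimental practice delimits regions by eye, so any
operationalization must pick explicit values. The defaults are the package's
choices, not a claim about the original procedure.

Synthetic reference sets (`simulate_reference_set()`) titrate a pure species
against free dye across photon fractions 0.35–1 (40 points), each measured
as a 1000-photon decay with bootstrap error bars. Two deliberate choices:
fractions below ~0.35 are omitted because there the titration phasor is
indistinguishable from free dye and would spuriously capture early
aggregation points; and the modest photon budget gives 2-sigma error bars
(~0.02–0.03) comparable to the scatter of real technical repeats and to the
reference spacing, so that points lying on the mixing chord actually
overlap it. Trajectory points keep their own (much smaller) high-photon
error bars.

A known limitation: segments in the oligomer-to-fibril *conversion* window
are genuine multi-species mixtures that can deviate from both references
and therefore be labelled Type-A even though they occur after the Type-B
epoch. The deviation-based Type-A definition cannot distinguish "early
species unlike either reference" from "mixture between references"; the
reported overlap fractions make such segments easy to spot.

# The aggregation generator

`integrate_kinetics()` solves the minimal sequential scheme

$$\mathrm{M} \xrightarrow{k_1} \mathrm{A} \xrightarrow{k_2}
  \mathrm{B} \xrightarrow{k_3} \mathrm{F},$$

(monomer, Type-A oligomer, Type-B oligomer, fibril, in monomer-equivalent
µM), optionally with an autocatalytic term $k_e \mathrm{M}\mathrm{F}$
feeding monomer consumption. Integration is fixed-step RK4 with step at most
$0.01/\max(\text{rates})$ on a grid refined to hit every requested output
time; the system is smooth and non-stiff at preset scales, and with
$k_e = 0$ the Bateman closed form of the linear chain serves as an
independent accuracy oracle in the tests (agreement to $10^{-6}$ relative;
mass conserved to machine precision).

Optics: each species carries a rotor decay signature, a photon weight
(detected FLIM photons per µM) and a plate-reader brightness per µM.
`species_to_decay()` unions the per-species components with amplitudes
scaled by concentration × photon weight and renormalizes — the
species-mixture reading of lifetime shifts, stated as an assumption: from a
decay alone one cannot tell microviscosity changes from binding to a
specific species. `species_to_intensity()` is the linear brightness sum; in
the presets brightness is carried almost entirely by fibrils, producing the
switch-on sigmoid. The intensity channel is noiseless by default with an
optional lognormal multiplicative noise.

## Presets and their calibration

The three presets emulate the qualitative phenotypes of wild-type
alpha-synuclein and two variants on the default 0–120 h grid (1 h sampling,
100 µM initial monomer):

| preset | k1 (1/h) | k2 (1/h) | k3 (1/h) | phenotype |
|---|---|---|---|---|
| `wt_like` | 0.15 | 0.10 | 0.055 | τm onset ≈ 2–3 h, intensity t50 ≈ 30 h |
| `a30p_like` | 0.15 | 0.10 | 0.021 | identical oligomerization, conversion slowed: onset unchanged, t50 + ~14 h |
| `dp1_like` | 0.03 | 0.02 | 0.014 | oligomerization and conversion both delayed, conversion more: onset + ~4 h, t50 + ~45 h |

The decay signatures are monomer 0.10 ns (single component, free rotor),
Type-A 0.20 ns (weight 0.5 — nearly silent, consistent with its weak
detectability), Type-B bi-exponential (0.3, 1.5 ns; weight 6) and fibril
bi-exponential (0.6, 2.2 ns; weight 12), with intensity brightness
(0, 0, 0.02, 1). Rates and weights were chosen once, at design time, so
that noiseless traces reproduce the target phenomenology (ordering of
lifetime onset vs intensity t50 and the variant deltas) and that the phasor
trajectory passes through the monomeric/Type-A corner, the Type-B mixing
chord and the fibril chord in that order; they are generator conditions,
not fitted quantities, and the tests treat them as frozen. The onset deltas
are smaller than the corresponding visual reads of noisy experimental data
(a 5%-of-range crossing on a smooth noiseless curve fires early); the
orderings, which are what the package asserts, are unaffected.

# Kinetics summaries

`detect_onset()` finds the first time a series exceeds
`baseline_mean + max(k·SD_detrended, min_rise·(max − baseline_mean))` for
`m` consecutive samples (defaults k = 3, m = 2, min_rise = 0.05, baseline =
first 3 samples), linearly interpolated to the crossing. Two refinements
make the rule well behaved on noiseless, smoothly rising series: the
baseline SD is computed on the *detrended* baseline (otherwise a drifting
baseline measures trend, not noise, and inflates thresholds inconsistently
between fast- and slow-rising variants), and the dynamic-range floor keeps
the threshold strictly above an infinitesimal rise when the SD is zero.
Both preserve time-shift equivariance and invariance under positive affine
scaling of the values. `t50()` is the interpolated half-rise between the
means of the first and last 10% of samples — no curve fitting, hence robust
to non-logistic shapes. `compare_variants()` tabulates onsets, t50s and
deltas against a reference variant.

# Pipeline, formats, problem sizes

`run_pipeline()` chains simulate (or ingest) → model-order selection and
fitting → bootstrap phasors → reference simulation → classification →
kinetics, writing CSVs plus the JSON configuration stamped with a
content hash. All randomness derives from the single run seed, so runs are
byte-reproducible; the log deliberately omits wall-clock timings and paths.
Externally supplied decays enter through a directory of decay CSVs and a
`manifest.json` (write JSON numbers at full precision, e.g.
`jsonlite::write_json(..., digits = 17)`, to keep the ingestion path
byte-equivalent to the simulation path).

Default problem sizes — 121 timepoints, 1024 bins, 5×10^5 photons per
timepoint, 50 bootstrap replicates, 40-point references at 1000 photons —
run the whole pipeline in well under a minute and were chosen as the
smallest sizes at which fit noise is irrelevant to the classification and
kinetics conclusions.

# What the generator does and does not emulate

It does emulate: Poisson photon statistics, periodic excitation with
IRF convolution and inter-pulse carryover, species-dependent rotor decay
signatures, fibril-gated switch-on intensity, and the three kinetic
phenotypes. It does not emulate: nucleation-polymerization kinetics (the
sequential first-order chain has no sharp lag or secondary nucleation
beyond the optional `ke` term), detector artifacts (afterpulsing,
dead time), background/scatter beyond an optional constant, dye-binding
competition or concentration-dependent quantum-yield effects, pixel-level
image structure, or biological repeat-to-repeat variability. Passing tests
therefore demonstrate the correctness and internal consistency of the
analysis chain under controlled conditions, not the biological accuracy of
any particular rate constant.
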
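# synflim

Fluorescence-lifetime analysis of amyloid aggregation monitored with
molecular-rotor dyes (thioflavin T and relatives), for researchers who
follow protein aggregation with a plate reader and a FLIM/TCSPC microscope
side by side.

Rotor dyes report aggregation twice over: their bulk **intensity** switches
on only when mature fibrils appear (the classic sigmoid with lag phase and
half-rise time t50), while their **fluorescence lifetime** lengthens as soon
as the dye's rotation is hindered — already in oligomers — so the
amplitude-weighted mean lifetime rises much earlier. Where the lifetime
trajectory sits in the phasor plane, relative to reference titrations of
preformed fibrils and stabilized oligomers, identifies *which* species is
being sensed.

`synflim` implements that entire analysis chain, plus a synthetic-data
generator so every step is testable against ground truth:

* **TCSPC simulation** — periodic excitation (80 MHz default), exact
  geometric handling of inter-pulse decay carryover, IRF convolution,
  Poisson noise, pixel-decay summation.
* **Decay fitting** — mono/bi/tri-exponential reconvolution by constrained
  Levenberg–Marquardt with Neyman weights and multi-start; model-order
  selection; the amplitude-weighted mean lifetime
  τm = Σαiτi / Σαi.
* **Phasor analysis** — first-harmonic g = Σ I cos(ωt)/Σ I,
  s = Σ I sin(ωt)/Σ I; closed forms g = 1/(1+(ωτ)²),
  s = ωτ/(1+(ωτ)²) on the universal circle (center (1/2, 0), radius 1/2);
  intensity-weighted mixture algebra; parametric-bootstrap 2σ error bars.
* **Region classification** — two-direction error-bar overlap against
  fibril / stabilized-oligomer reference sets, segments labelled fibrillar,
  Type-B oligomeric or Type-A oligomeric under a 60% overlap rule.
* **Kinetics** — lifetime onset, intensity lag and t50, channel delay, and
  cross-variant comparisons, with generator presets emulating wild-type-,
  A30P- and ΔP1-like aggregation phenotypes.

## Worked example

```r
library(synflim)

# acquisition geometry: 80 MHz excitation, 1024 bins over one 12.5 ns period
cfg <- acq_config(n_bins = 1024)
irf <- make_gaussian_irf(fwhm_ns = 0.2, center_ns = 1, config = cfg)

# simulate a rotor decay: 60% of the signal amplitude from a 0.3 ns
# environment, 40% from a 2.0 ns environment, one million photons
truth <- decay_model(c(0.6, 0.4), c(0.3, 2.0))
h <- simulate_decay(truth, irf, cfg, total_photons = 1e6, seed = 7)

select_model(h, irf, seed = 1)
#> <fit_result> n = 2, tau_m = 0.9785 ns, chi2_red = 1.071, converged = TRUE

phasor_uncertainty(h, n_replicates = 50, seed = 2)
#> <phasor_point> g = 0.30577 +/- 0.00133, s = 0.66208 +/- 0.00064

universal_circle_distance(phasor_from_lifetime(2.0, cfg$angular_frequency))
#> [1] 0.5
```

The fitted τm of 0.9785 ns recovers the ground truth
0.6·0.3 + 0.4·2.0 = 0.98 ns; the single-lifetime phasor sits exactly on the
universal circle (measured phasors are rotated by the IRF delay, which is
why trajectories and references are always compared in the same measured
space).

A whole synthetic aggregation experiment, fitted and classified end to end:

```r
res <- run_pipeline(run_config(preset_name = "wt_like", seed = 42), "out")

head(res$regions[, 1:5], 4)
#>   segment_start segment_end             label overlap_fibril overlap_oligomer
#> 1             1           5 type_a_oligomeric              0              0.4
#> 2             6          10 type_b_oligomeric              0              1.0
#> 3            11          15         fibrillar              1              0.6
#> 4            16          20         fibrillar              1              0.0

res$kinetics[, c("variant", "tau_m_onset_h", "intensity_t50_h", "channel_delay_h")]
#>   variant tau_m_onset_h intensity_t50_h channel_delay_h
#> 1 wt_like      1.896461        30.37703        28.48057
```

The trajectory moves through the monomeric/Type-A corner into the Type-B
oligomeric region and on to the fibrillar region, and the fitted lifetime
onset (~1.9 h) precedes the intensity half-rise (~30 h) by more than a day —
the early-detection effect the lifetime channel exists for. `out/` contains
the trace, fit, phasor, region, reference and kinetics CSVs, the JSON
configuration (content-hashed) and a deterministic log.

A thin command-line wrapper with subcommands `simulate`, `fit`, `phasor`,
`classify`, `kinetics` and `run` is installed under
`system.file("cli/synflim", package = "synflim")`.

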
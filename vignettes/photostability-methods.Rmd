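---
title: "Models and methods behind fretstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretstab)
```

# Scope

`fretstab` re-implements, as a tested pipeline, the photo-stability analysis
of Cy3/Cy5-labeled DNA constructs observed by single-molecule FRET (smFRET):
a photophysics simulator that generates donor/acceptor intensity trajectories
(standing in for raw EM-CCD movies, which are not publicly available), an
optional image-level forward/inverse path, FRET conversion-event detection and
classification, single-exponential photobleach survival fitting, and
nearest-neighbor duplex melting thermodynamics. This vignette documents the
models, the tunable parameters, the numerical choices, and what the synthetic
data do and do not establish about real measurements.

# The photophysics model

Cyanine dyes (Cy3, Cy5) are polymethine chromophores whose excited singlet
state can rotate about a C–C bond to a *twisted intermediate*. From there the
molecule branches back to the bright all-trans ground state, to a
non-fluorescent *cis* ground state (blinking), or — via intersystem crossing —
to the triplet T1, the gateway to irreversible photodegradation. Rigid
insertion of the dye into the duplex sugar-phosphate backbone sterically
hinders the twist, which is the proposed mechanism for the enhanced
photo-stability of internally labeled constructs.

`photophysics_params()` parameterizes this scheme with per-excitation-cycle
probabilities. Because excitation cycles (microseconds) are ~10^3–10^4 times
faster than a camera frame (100 ms) and ~10^6 times faster than bleaching
(minutes), the simulator never resolves individual cycles. Instead it
aggregates them analytically into per-second hazards:

* bleaching: `k_eff = excitation_rate × rigidity × p_isomerize × p_isc × p_bleach_T1`,
* blinking (cis entry): `k_dark = excitation_rate × rigidity × p_isomerize × p_cis`,

draws event times as exponential/telegraph dwell sequences in continuous
time, and rasterizes them onto the frame grid (frame value = state at frame
start). This coarse-graining is exact for the observables the pipeline uses:
bleach times are exponential with hazard `k_eff` *by construction*, which the
test suite verifies by Kolmogorov–Smirnov tests against the closed-form
exponential CDF. An event-time (Gillespie-style) draw rather than per-frame
Bernoulli thinning also avoids the O(dt) discretization bias of
`1 − exp(−k·dt)` per-frame sampling.

No numeric rates for this scheme have been published — the potential-energy
surfaces behind it are explicitly hypothetical — so the defaults are declared
package choices, not inferred quantities: `excitation_rate = 1e4 s⁻¹`,
`p_isomerize = 3.617e-3`, `p_isc = 0.1`, `p_bleach_T1 = 1e-3`, which combine
to `k_eff = 0.217 min⁻¹` at `rigidity = 1` — anchoring the externally labeled
reference construct to its measured 22 mW bleach rate. `p_cis = 1e-4` with
`dark_recovery_rate = 20 s⁻¹` gives rare ~50 ms dark states, the regime
expected when blinking is suppressed by triplet-quencher/oxygen-scavenger
buffers; `quantum_yield_bright = 0.4` gives ~400 detected counts per 100-ms
frame.

## Construct presets

`construct_preset()` calibrates the four studied constructs so that the
ensemble pair-bleach rate constant (acceptor hazard + donor hazard) equals the
measured 22 mW photobleach rate:

| preset | k_pair (min⁻¹) | rigidity | acceptor share | breathing open rate (s⁻¹) |
|---|---|---|---|---|
| eCy3/eCy5-duplex | 0.217 | 1.000 | 0.90 | 4.98e-4 |
| endCy3/iCy5-pt   | 0.189 | 0.871 | 0.47 | 2.71e-4 |
| iCy3/iCy5-fork   | 0.112 | 0.516 | 0.45 | 2.37e-4 |
| iCy3/iCy5-duplex | 0.066 | 0.304 | 0.04 | 2.5e-5  |

Rigidity is expressed relative to the external label and reproduces the
predicted stability ordering (internal duplex > fork > primer/template end >
external). The *acceptor share* splits the pair hazard between the two dyes so
that the expected fraction of molecules showing an irreversible conversion
(acceptor bleach, visible as an anticorrelated FRET drop) within a 120 s
acquisition matches the measured irreversible-conversion percentages; the
breathing open rates are set so the probability of at least one reversible
excursion in 120 s matches the measured reversible percentages. These are
fixed generator conditions, not fitted quantities. Note one deliberate
rounding choice: the internally duplex-labeled preset pins the *rate
constant* (0.066 min⁻¹, i.e. τ = 15.15 min) rather than the printed τ of
15.0 min, since the printed pair is itself rounded (1/0.066 ≠ 15.0).

Laser power enters only through `excitation_rate` (`scale_power()`), so every
per-cycle hazard — bleaching and blinking alike — scales linearly with power.
The measured power series (0.066 → 0.037 → 0.029 min⁻¹ for 22 → 16 → 10 mW)
is slightly sub-linear at the lowest power; the linear model overpredicts
0.030 vs 0.029 min⁻¹ at 10 mW. `scale_power()` therefore exposes an optional
`power_exponent` for sub-linear laws, with the linear default.

## Breathing and noise

DNA breathing — long-lived local duplex opening near forks and
primer/template junctions — is a two-state telegraph process between a closed
conformation (`E_closed = 0.75` by default) and an open one
(`E_open = 0.25`). The default mean open dwell of 2 s places excursions well
inside the ~20 s recovery window, as observed: reversals happen within a few
seconds of the forward step.

Detected counts use Poisson shot noise by default (`noise_model = "poisson"`).
EM-CCD electron-multiplying registers roughly double the shot-noise variance;
`"poisson_emgain"` models this with a unit-mean gamma multiplier
(output ~ Gamma(shape = photon count, rate = 1)). Background counts and
channel crosstalk default to 0 — neither is quantified for the original
instrument — and are configurable. Throughout the package "SNR" means the
per-frame shot-noise ratio of the summed two-channel intensity,
`SNR = sqrt(I_D + I_A)`; a cohort at SNR 10 has 100 counts/frame.

# Event detection and classification

The FRET efficiency is `E = I_A / (I_D + I_A)`; frames whose summed intensity
falls at or below `signal_floor` (both dyes dark) are undefined rather than
divided. A *FRET conversion event* is a precipitous drop in E with a
simultaneous acceptor decrease and donor increase. The published analysis
states no numeric threshold, so the detector's definition is exposed
configuration (`event_config()`) with documented defaults:

* a drop of at least `delta_E_min = 0.3` in E,
* completed within `max_transition_frames = 3` frames,
* persisting at least `min_dwell_frames = 5` frames,
* with the acceptor-down and donor-up steps each at least
  `anticorr_sigmas = 3` robust noise SDs (MAD of frame differences, scaled to
  the window mean).

Detection runs a matched step filter (difference of 5-frame means across a
3-frame gap, computed by cumulative sums), groups super-threshold indices,
refines each onset to the steepest single-frame drop, and merges candidates
closer than one dwell window. The anticorrelation requirement is what
separates conversions from blinks (both channels drop) at negligible cost in
sensitivity. A *sustained* (≥ `min_dwell_frames`) drop of both channels below
the signal floor is emitted as a donor-bleach event instead and ends the
conversion search; shorter dark gaps are treated as blinks and bridged by
carrying the last defined E forward.

Acceptor blinks are anticorrelated too — the acceptor goes dark while the
donor brightens — so amplitude alone cannot separate them from breathing.
The detector therefore discards "conversions" that recover faster than
`min_event_duration_s = 0.5` s as blinks: cis dark states under
triplet-quenched conditions last tens of milliseconds, whereas the breathing
excursions of interest last seconds. The cost is that genuinely brief
breathing excursions (shorter than ~0.5 s) are also discarded, which is why
preset-simulated fields report slightly fewer reversible events than the raw
excursion rate would suggest (bleaching truncating the observation window
accounts for most of the rest).

Recovery is the first instant E returns within `recovery_tol = 0.15` of its
pre-event level for at least `min_dwell_frames`. A conversion recovering
within `recovery_window_s = 20` of onset — **inclusive** at exactly 20 s,
a declared convention since the published criterion is "~20 s" — is
*reversible* (attributed to breathing); otherwise it is *irreversible*
(attributed to acceptor photobleaching). At SNR 10 and drop 0.5 the detector's
E-threshold sits ~11 noise SDs above baseline, so false positives are
negligible and sensitivity is effectively 1; the suite verifies sensitivity
and specificity ≥ 0.95 down to drop 0.4 at SNR 5.

`summarize_field()` reports the percentage of molecules with ≥ 1 event of
each class, with means and SDs across experiment groups (SD is `NA`, not 0,
for a single experiment). A molecule with both classes counts once, as
irreversible — bleaching terminates its observation — which keeps
total = irreversible + reversible additively, matching the published table
structure. How such molecules were originally tallied is not stated; this
tie-break is a declared convention.

# Survival analysis

`count_active_pairs()` counts molecules still active per time bin (default
10 s bins). Activity is molecule-level, derived from classified events —
identical to per-frame re-detection for synthetic data and far cheaper; the
imaging module provides the per-frame alternative for round-trip validation.
Under the default `acceptor_alive` rule a pair dies at its first irreversible
conversion or donor bleach; blinking gaps shorter than 2 frames never
terminate activity. Whether the original curves came from per-frame
re-detection or tracked survival is not stated; both paths exist here, with
tracked survival the default.

`fit_exponential()` fits `N(t) = N0·exp(−t/τ_B)` by nonlinear least squares
(initialized at `N0 =` first-bin count, `τ =` half the last time; `nls` with
a Levenberg–Marquardt fallback), and derives `k_B = 1/τ_B` and
`t_1/2 = τ_B·ln 2` exactly. It separately fits the ordinary least-squares
slope of `log10(N)` vs time over bins with `N ≥ 1` (log of zero is
undefined), reporting slope, SE and R² — the second fit style used for these
data. The two are internally consistent (`log_slope ≈ −k_B/ln 10`) on clean
input but are independent fits on noisy data, and no equality between them is
asserted. Non-decaying or all-zero curves raise an identifiability error
rather than a fit. Poisson (1/N) weighting is available but off by default;
it does not materially improve τ recovery because survival-bin errors are
serially correlated, not independent.

One statistical note: at a field size of 400 molecules the information bound
for any unbiased τ estimator is a 5% relative SD (√400), so no estimator can
place τ within 10% of truth in appreciably more than ~95% of replicates; the
binned curve fit is unbiased with ~5.6% SD (~93% within 10%). The package's
parameter-recovery test asserts unbiasedness and near-bound spread at n = 400;
headline recovery checks use n = 2,000, where the 10% band is comfortable.

# The imaging path

`render_movie()` is the forward model: fixed molecule positions (drawn with
minimum separation 4·σ_PSF), Gaussian PSFs (σ default 1.2 px) truncated at
4σ, a donor half-sensor and an acceptor half-sensor related by a rigid
`channel_offset`, constant mean background, Poisson pixel noise. Coordinates
are 0-based pixel centers with x = column, y = row, everywhere.
`detect_spots()` matched-filters with the PSF, thresholds local maxima at
5 robust SDs of the filtered image, and refines positions by centroid.
`pair_channels()` does greedy globally-nearest matching after the offset
(order-invariant); `extract_trajectories()` sums fixed circular apertures
(default radius 4 px, ≈ 99.6% of the PSF mass at σ = 1.2) minus the median of
out-of-aperture pixels. The original detection software (IDL) is not
described; this module is a declared stand-in validated only against the
synthetic forward model — detection recall/precision ≥ 0.99 at 400
molecules/field, FRET round-trip error < 0.02, event labels preserved.

# Melting thermodynamics

`nn_tm()` sums unified nearest-neighbor ΔH°/ΔS° stacks (pinned, versioned
parameter file `inst/extdata/nn_unified_v1.csv`) with per-terminal initiation
terms and computes the two-state bimolecular melting temperature
`Tm = ΔH / (ΔS + R·ln(C_T/4))` (C_T/1 plus the symmetry entropy for
self-complementary duplexes). Salt enters through the entropy correction
`ΔS + 0.368·(N−1)·ln[Na⁺_eq]`; Mg²⁺ is folded into a monovalent equivalent
as `[Na⁺] + 120·√([Mg²⁺]/mM)` mM — a documented convention, since the exact
divalent treatment of the original prediction server is unstated. The engine
is verified to < 0.01 °C against an independently computed oracle on five
fixed duplexes, and for orientation symmetry and salt/concentration
monotonicity.

Internal dye insertions were originally predicted by placing a dA–dG
mismatched pair at the probe site. Context-dependent dA–dG mismatch stack
parameters are not bundled here; instead each declared insertion site adds a
fixed destabilization penalty (ΔΔH = +2.4 kcal/mol, ΔΔS = +4.55 cal/mol·K,
≈ +0.7 kcal/mol at 37 °C), calibrated once against the ~0.5–0.7 °C predicted
single-insertion depressions and then frozen; results carry an
`insertion_penalty_applied` flag. The construct sequences themselves are not
in the public text, so end-to-end reproduction of the predicted-Tm column is
out of scope; the representative duplex used in `analysis/05_melting.R` is
synthetic and labeled as such.

`extract_tm_from_curve()` takes the maximum of the smoothed (5-point moving
average) first derivative of an absorbance melting curve, with parabolic
sub-grid refinement — accurate to < 0.5 °C on 1 °C grids for noise up to 2%
of the hyperchromic amplitude. `delta_tm_summary()` averages
`Tm(labeled) − Tm(unmodified)` over matched buffers and rounds to 0.1 °C;
on the in-repo measured-Tm table it yields −2.7 °C (internal) and −6.5 °C
(external), the central thermodynamic result.

# What the synthetic data do and do not show

The generator emulates the study conditions: ~400 molecules per field, 100-ms
frames, 120-s acquisitions, construct-dependent exponential bleach hazards,
rare reversible breathing excursions, donor vs acceptor bleaching and
blinking, shot/EM noise. It does **not** emulate spectral crosstalk between
channels, gamma-distributed per-molecule brightness, stage drift, non-uniform
illumination, surface heterogeneity, or multi-step photobleaching — so green
tests demonstrate that the *analysis machinery* is correct and calibrated,
not that the detector would achieve the same sensitivity on raw instrument
data. Conversion percentages are reproduced by construction (events are
injected at the published fractions and must survive detection), which
validates detection/classification/summary, not the underlying photochemistry.

# Problem sizes and runtime choices

The test suite and acceptance script use 2,000-molecule ensembles for
survival fits (estimator SD ~2.2%, comfortably inside the 10% comparison
band) and 4,000-trajectory cohorts at 1,200 frames for event statistics —
the sizes at which the published percentages were tallied (1,000–4,000 events
per construct). Imaging tests use small sensors (64–128 px) except for one
full-density 512 × 256 recall/precision check; rendering full fields for
every test would add minutes without changing coverage. All randomness is
seeded; two runs with the same seed are bitwise identical.
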
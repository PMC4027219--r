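# fretstab

Photo-stability analysis of Cy3/Cy5-labeled DNA constructs observed by
single-molecule FRET (smFRET).

## The problem

In smFRET experiments on DNA, a drop in acceptor (Cy5) intensity with a
simultaneous rise in donor (Cy3) intensity — a *FRET conversion event* — is
the signature of a biologically interesting conformational change. But
acceptor photobleaching produces exactly the same signature. Distinguishing
the two matters enormously for how the dyes are attached: chromophores
rigidly inserted into the duplex sugar-phosphate backbone ("internal"
labeling) photobleach far more slowly and show far fewer spontaneous
conversion events than dyes tethered to bases by flexible linkers
("external" labeling), while perturbing duplex stability less.

`fretstab` provides the full analysis chain for quantifying this, for anyone
simulating or analyzing two-channel single-molecule intensity trajectories:

* a **photophysics simulator** (`simulate_field()`, `simulate_pair()`) built
  on a coarse-grained photoisomerization/triplet scheme — excitation drives
  the dye to a twisted intermediate that branches to bright *trans*, dark
  *cis* (blinking), or the triplet T1 from which irreversible
  photodegradation occurs — with per-dye hazards
  `k_eff = excitation_rate · rigidity · p_isomerize · p_isc · p_bleach_T1`,
  two-state DNA-breathing FRET modulation, and Poisson/EM-gain noise;
* an **imaging path** (`render_movie()`, `detect_spots()`,
  `pair_channels()`, `extract_trajectories()`) that renders split-sensor
  TIRF-like movies and recovers trajectories by matched-filter spot
  detection and aperture photometry;
* **event analysis** (`detect_conversion_events()`, `classify_events()`,
  `summarize_field()`): FRET efficiency `E = I_A/(I_D + I_A)`, step-filter
  detection of anticorrelated drops, and the ~20 s recovery criterion that
  separates *reversible* events (local DNA "breathing") from *irreversible*
  ones (acceptor photobleaching);
* **survival analysis** (`count_active_pairs()`, `fit_exponential()`,
  `compare_power_series()`): active-pair counts vs illumination time, the
  single-exponential fit `N(t) = N₀·e^(−t/τ_B)` with `k_B = 1/τ_B` and
  `t_1/2 = τ_B·ln 2`, and the log₁₀-linear slope fit;
* **melting thermodynamics** (`nn_tm()`, `extract_tm_from_curve()`,
  `delta_tm_summary()`): unified nearest-neighbor Tm prediction with salt
  correction and dye-insertion penalties, derivative-based Tm extraction
  from UV melting curves, and ΔTm summaries against the unmodified duplex.

## Worked example

Simulate a field of 400 externally labeled duplex constructs (100-ms frames,
120 s, 22 mW equivalent), detect and classify conversion events, and fit the
photobleach decay of a 2,000-molecule ensemble at the same hazard:

```r
library(fretstab)

field  <- field_spec(n_molecules = 400, dt = 0.1, duration = 120, seed = 11)
trajs  <- simulate_field(field, "eCy3/eCy5-duplex")
events <- classify_field_events(trajs)
summarize_field(events)
#> <field_event_summary> 400 molecules in 1 experiment(s)
#>   total conversions:   35.5%
#>   irreversible:        33.2%
#>   reversible:          2.2%

set.seed(11)
bt <- simulate_bleach_times(2000, 0.217)          # hazard in min^-1
fit_exponential(count_active_pairs(bt, duration_min = 30))
#> <decay_fit>
#>   tau_B = 4.511 min   k_B = 0.2217 min^-1   t_1/2 = 3.127 min
#>   log10 fit: slope = -0.09713 min^-1 (SD 0.00036), R^2 = 0.9976

delta_tm_summary(duplex_tm_measured())
#>   construct mean_delta_tm_c n_buffers
#> 1 eCy3_eCy5            -6.5         3
#> 2 iCy3_iCy5            -2.7         3
```

Reading the output: roughly a third of externally labeled molecules show a
conversion event within 120 s, overwhelmingly irreversible (acceptor
photobleaching) with a small reversible (breathing) fraction (a
2,000-molecule run of the same preset converges to 31.9% / 2.8%); the ensemble
bleaches with a ~4.5 min time constant (~3.1 min half-life); and the melting
table shows internal labels destabilize the duplex by only −2.7 °C on
average — about the size of a single base-pair mismatch — versus −6.5 °C for
external labels. The internally duplex-labeled preset (`"iCy3/iCy5-duplex"`)
bleaches ~3× more slowly and is nearly conversion-free (< 1%).

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
study's analyses end-to-end with simulated data, writing tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate_fields.R` | one field per construct preset → trajectory CSVs |
| `02_photobleach_survival.R` | survival curves, exponential + log fits, power series |
| `03_conversion_events.R` | event injection, detection, field percentages |
| `04_imaging_roundtrip.R` | render → detect → extract → classify round trip |
| `05_melting.R` | ΔTm summary, NN predictions, melting-curve Tm extraction |

Run them in order with `Rscript analysis/01_simulate_fields.R` etc. The
methods vignette (`vignettes/photostability-methods.Rmd`) documents the
models, parameter choices and limitations.

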
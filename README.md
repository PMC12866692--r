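# flockmetrics

Quantitative analysis of collective cell migration in dense epithelial
monolayers: from time-lapse microscopy (or cell tracks) to a four-state
mechanical classification — jammed solid, unjammed disordered fluid,
flocking fluid, or flocking solid.

Epithelial tissues switch between arrested (jammed) and motile
(unjammed) states, and motile tissues can additionally *flock*: migrate
with long-range velocity alignment, with or without exchanging cell
neighbors. `flockmetrics` implements the measurement chain that makes
these distinctions operational, for experimentalists analyzing
monolayer streaming assays and for modelers validating active-matter
simulations:

- **PIV** (`compute_piv`): zero-normalized cross-correlation particle
  image velocimetry with Gaussian subpixel refinement and
  normalized-median outlier validation; or coarse-grained track
  velocities (`field_from_tracks`) when only tracks are available.
- **Kinematics** (`motility_time_series`): center-of-mass velocity
  V<sub>cm</sub> = ⟨v<sub>i</sub>⟩, root-mean-square velocity
  V<sub>RMS</sub> = √⟨|v<sub>i</sub>|²⟩, the flocking order parameter
  ψ = |⟨v<sub>i</sub>⟩| / √⟨|v<sub>i</sub>|²⟩ ∈ [0, 1], track-based
  V<sub>RMS-CM</sub>, framecut means and motility-peak windows.
- **Velocity correlation length** (`correlation_over_window`):
  FFT-based spatial autocorrelation of the drift-corrected velocity
  field, radially averaged and fitted with the stretched exponential
  C(r) = exp(−(r/L<sub>corr</sub>)<sup>γ</sup>).
- **Neighbor exchange** (`radial_distribution`,
  `first_valley_threshold`, `neighbor_distance_curve`): RDF-derived
  neighbor threshold, the tagged-neighbor distance d(δt) and its growth
  rate (zero for solids, positive for fluids), and the neighbor
  displacement probability map P(r, δt).
- **Density dynamics** (`local_density`, `density_kymograph`,
  `density_fluctuation_map`): 50 µm-kernel density fields, kymographs
  and temporal fluctuation maps.
- **Shape metrics** (`shapes_from_mask`): aspect ratio and shape index
  p/√A from label masks, their population SDs, size-filtered normalized
  aspect-ratio time series, and the dual-color cell-cycle (G2/M)
  fraction.
- **Assay quantification** (`detect_bleach_region`,
  `normalize_recovery`, `fit_frap_recovery`, `wetting_curve`): FRAP
  bleach-disc detection, double-normalized recovery curves and
  single-exponential fits; normalized spheroid-spreading (wetting)
  curves.
- **State classification** (`classify_state`): an explicit rule table
  over (V<sub>RMS</sub>, L<sub>corr</sub>, exchange slope) with
  recorded thresholds, so every call is reproducible from its own
  provenance.
- **Synthetic ground truth** (`simulate_monolayer`,
  `make_regime_config`, `render_frames`, `simulate_frap_stack`,
  `simulate_wetting_areas`): an overdamped Vicsek-type
  self-propelled-particle monolayer with soft repulsion and optional
  harmonic bonds, with presets that realize all four dynamic states,
  plus synthetic image rendering and FRAP/wetting generators — so the
  entire pipeline is testable without experimental data.

The methods vignette
(`vignettes/flocking-monolayer-analysis.Rmd`) documents the model
definitions, parameter defaults, numerical choices, and limitations.

## Worked example

Simulate a flocking monolayer (400 cells, 12 h at 5-min frames) and run
the full analysis:

```r
library(flockmetrics)

cfg    <- make_regime_config("flocking_fluid", seed = 7)
tracks <- simulate_monolayer(cfg)
report <- run_pipeline(tracks = tracks)
report
#> <pipeline_report>
#>   field              ok
#>   motility           ok
#>   framecut_summary   ok
#>   correlation        ok
#>   neighbors          ok
#>   density            ok
#>   shape              failed: no masks (not computed: no segmentation)
#>   state              ok
#>   state: flocking_fluid

m <- report$metrics
sprintf("V_RMS = %.1f um/h, psi = %.2f, L_corr = %.1f um, exchange slope = %.2f um/h",
        m$v_rms, m$psi, m$l_corr, m$exchange_slope)
#> [1] "V_RMS = 28.0 um/h, psi = 0.96, L_corr = 36.2 um, exchange slope = 0.28 um/h"

report$state
#> <tissue_state_call> flocking_fluid
#>   L_corr 36.2 >= 14.0 um and exchange slope 0.284 >= 0.150 um/h: coordinated with neighbor exchange
```

Reading the numbers: the monolayer is fast (V<sub>RMS</sub> ≈ 28 µm/h —
far above the 2 µm/h arrest threshold), strongly aligned (ψ ≈ 0.96;
velocity fluctuations stay correlated over L<sub>corr</sub> ≈ 36 µm,
several cell diameters), and its cells drift away from their initial
neighbors at ≈ 0.3 µm/h — so it is a *flocking fluid*: coordinated
migration with ongoing neighbor exchange. A `jammed_solid` preset run
gives V<sub>RMS</sub> ≈ 0.3 µm/h and is classified as arrested; the
bonded `flocking_solid` preset is equally fast and aligned but its
exchange slope stays below 0.15 µm/h.

Individual stages are ordinary functions; e.g. PIV on rendered images:

```r
stack <- render_frames(tracks, pixel_size = 1, psf_sigma = 3, seed = 7)
field <- compute_piv(stack, piv_params(window_size = 50,
                                       overlap_fraction = 0.5))
motility_time_series(field)
```

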
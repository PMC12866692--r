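---
title: "Quantifying jamming, unjamming and flocking in epithelial monolayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying jamming, unjamming and flocking in epithelial monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockmetrics)
```

## The scientific problem

Dense epithelial monolayers switch between mechanically distinct dynamic
states. A *jammed solid* is arrested: cells barely move, keep their
neighbors, and deform little. An *unjammed, disordered fluid* is motile
but spatially uncoordinated. A *flocking fluid* combines high motility
with long-range velocity alignment and ongoing neighbor exchange, and a
*flocking solid* moves collectively while retaining its neighbor
topology — coordinated migration of a tissue that is still, structurally,
a solid. Growth-factor signaling, cell density, and gap-junctional
communication all shift monolayers between these states, so a
reproducible, quantitative readout of "which state is this tissue in?"
is the core measurement problem this package addresses.

`flockmetrics` implements the full measurement chain from time-lapse
microscopy (or cell tracks) to a four-state call, together with a
self-propelled-particle simulator that generates labeled ground truth in
each state so that every stage of the chain can be validated without
experimental data.

## Kinematic observables

Velocities are measured on a regular grid, either by cross-correlation
PIV on image pairs (`compute_piv()`) or by coarse-graining tracked cell
centroids (`field_from_tracks()`). From the grid of window velocities
$v_i(t)$ the package computes, per frame:

* center-of-mass velocity $V_{cm}(t) = \langle v_i(t) \rangle_i$;
* root-mean-square velocity
  $V_{RMS}(t) = \sqrt{\langle |v_i(t)|^2 \rangle_i}$, the total-motility
  readout. A drift-corrected variant subtracts $V_{cm}$ first; the
  default reports the plain RMS, matching the convention of headline
  motility curves, while the correlation analysis always works with
  drift-corrected velocities;
* the order parameter
  $\psi = |\langle v_i \rangle_i| / \sqrt{\langle |v_i|^2 \rangle_i}$,
  which is 1 exactly when all windows move with identical velocity and
  $\mathcal{O}(N^{-1/2})$ for randomly oriented motion. A second variant,
  $|\langle v \rangle| / \langle |v| \rangle$, normalizes by the mean
  speed instead of the RMS speed; the two coincide for equal speeds and
  the RMS-normalized form is never larger (Cauchy–Schwarz vs. the
  triangle inequality). The RMS-normalized form is the default because
  its $\psi = 1$ limit demands equal speeds *and* directions; the other
  is reported alongside in `motility_time_series()`.

The track-based counterpart `track_rms_cm_velocity()` computes the RMS
of per-cell centroid velocities, a local-fluctuation readout that does
not average within windows.

Summary statistics are taken over a *framecut*, a fixed time window
(default 15–40 h) chosen to cover the steady migratory phase;
`find_motility_peak()` locates the motility maximum on a smoothed
$V_{RMS}$ series and returns a window (default 10 h — the length is a
package choice, configurable) over which the spatial correlation is
averaged.

## Velocity correlation length

Spatial coordination is quantified by the equal-time velocity
autocorrelation, computed with the Fourier method:
$C(\delta) = \mathcal{F}^{-1}\!\left(|\mathcal{F}(v_x)|^2 +
|\mathcal{F}(v_y)|^2\right)/N$, under the periodic convention, which is
exactly the average over all circular shifts (this identity is tested
against a brute-force oracle on every grid up to 16×16). Because
coherent drift inflates the correlation at all distances, the squared
mean velocity is subtracted (equivalently, velocities are
drift-corrected before transforming — the default), and the curve is
normalized by its corrected zero-lag value so it starts at 1.

After radial averaging, the decay is fitted with a stretched exponential
$C(r) = \exp(-(r/L_{corr})^{\gamma})$ with bounds $L > 0$ and
$\gamma \in (0, 2]$, initialized at the interpolated $1/e$ crossing.
$\gamma = 1$ recovers the plain exponential; the stretching exponent
absorbs the mild non-exponentiality of monolayer correlation curves.
The fit excludes the zero-lag bin (self-correlation) and lags beyond
half the grid extent (periodic aliasing); it reports convergence, and a
degenerate input (e.g. a uniform field whose fluctuations vanish) yields
an explicit not-converged record rather than a number.

Numerical choices worth knowing:

* radial bins are centered on multiples of the bin width
  (nearest-center assignment), so the zero lag sits in a bin centered
  exactly at 0 and is cleanly excluded from fits;
* the periodic (no-padding) convention matches the simulator's periodic
  box; for bounded experimental fields the same estimator is applied to
  the interior grid, where wraparound mixes distant windows — with the
  fit restricted to lags below half the extent this bias is second
  order;
* invalid velocity vectors are inpainted by the median of valid
  neighbors before transforming; frames with more than 30% invalid
  vectors are rejected (window averages skip them and report how many
  frames were used; the average fails only when no frame is usable).

Validation: on spectrally synthesized Gaussian velocity fields whose
periodic correlation is exactly the minimum-image $e^{-r/L}$ (white
noise filtered with the discrete spectrum $S = \mathcal{F}(e^{-r/L})$),
the chain (FFT → radial average → fit) recovers
$L \in \{20, 50, 100\}$ µm on 512×512 grids within 15% and $\gamma$
within 0.15 of 1 (medians over 20 seeds). Two estimator facts surfaced
by this exercise are worth knowing: synthesizing with the *continuum*
spectrum $(1 + (kL)^2)^{-3/2}$ does not produce $e^{-r/L}$ on a finite
periodic grid once $L$ is an appreciable fraction of the box, and
subtracting the per-realization sample mean (rather than the known
ensemble mean) imposes a sum-zero constraint on the empirical
correlation that biases $L$ downward for large $L/\mathrm{box}$ —
which is why drift correction matters for real drifting tissue but is
skipped for zero-mean synthetic ensembles.

## PIV

`compute_piv()` is a single-pass zero-normalized cross-correlation PIV:
50 µm interrogation windows (about five cells) with 50% overlap by
default, 3-point Gaussian subpixel peak refinement, a normalized-median
outlier test (threshold 2.0, regularization 0.1 px — community
defaults), and a peak-ratio signal-to-noise floor. Invalid vectors are
replaced by the median of valid neighbors and flagged, never silently
zeroed. Two implementation details matter for accuracy:

* the correlation is *linear* (zero-padded), with each lag normalized by
  its overlap area. A circular correlation without padding under-weights
  nonzero lags whenever the window content is not periodic, biasing
  displacements toward zero by more than 0.1 px at half-pixel
  displacements;
* windows that do not fully fit in the frame are dropped, not padded,
  avoiding spurious low velocities at the borders.

Multi-pass window deformation is out of scope; at the displacement scale
of monolayer movies (a few pixels between 5-min frames) a single pass
with subpixel refinement recovers integer shifts exactly and a rendered
half-pixel drift within 0.1 px.

## Neighbor exchange

Neighbors are defined from the data, not by a fixed radius: the radial
distribution function $g(r)$ of cell positions is computed
(minimum-image in the periodic box for synthetic data; guard-region edge
correction for bounded fields of view) and the first valley of the
smoothed curve after its first peak sets the neighbor distance
threshold. The peak must exceed 1.2, and the valley must fall either
below 1 or below 75% of the peak height — together this rejects
sampling noise around the ideal-gas level and shoulder artifacts while
accepting the shallow first valley of strongly overlapping soft-disc
packings; a structureless (ideal-gas-like) pattern raises an error
advising a manual threshold. The pipeline averages $g(r)$ over five
frames spread through the movie before locating the valley, since
single-frame RDFs of evolving packings are noisy. Cells strictly closer
than the threshold are neighbors.

The exchange statistic follows the tagged-neighbor construction: assign
neighbors at a reference time $t$, then measure the mean distance
$d(\delta t)$ between each cell and *those same* neighbors a delay
$\delta t$ later, weighting cells by $1/N(t)$ and each cell's neighbors
by $1/n_i(t)$, and averaging over all valid reference times. Its shifted
form $\Delta d(\delta t) = d(\delta t) - d(0)$ starts at zero; its
linear growth rate (least-squares slope) is the neighbor-exchange
readout: zero for solids (neighbors retained even while the tissue
drifts), positive and roughly linear for fluids. Both $d$ and $\Delta d$
are reported; classification uses the slope of $\Delta d$. The companion
probability map `neighbor_displacement_map()` histograms the change in
relative position of tagged neighbor pairs, normalized to unit integral.

Exact invariants are enforced by tests: rigid translations and rotations
leave $\Delta d$ at zero to $10^{-12}$; the vectorized implementation
matches a brute-force $O(N^2)$ oracle to $10^{-12}$ on 200-cell
instances; a hexagonal lattice yields a threshold between $a$ and
$a\sqrt{3}$ and exactly six interior neighbors. Track gaps of up to 3
frames are closed by linear interpolation (matching common gap-closing
tracker settings); longer gaps break the pair, and dropped pairs are
counted.

## Density fields, shape metrics, assays

`local_density()` counts cells within a 50 µm disc around each grid
point (grid spacing defaults to a fifth of the radius), divided by the
clipped-disc area near bounded edges or using minimum-image distances in
the periodic box. Kymographs collapse the field along one axis;
`density_fluctuation_map()` is the per-pixel temporal SD — flat for
homogeneous dynamics, elevated along the paths of traveling density
waves.

Shape descriptors come from label masks: area as pixel count, ellipse
axes from second central moments (the "fit ellipse" convention, so a
solid ellipse's fitted axes equal its true axes), and perimeter as the
sub-pixel contour length of the Gaussian-smoothed ($\sigma$ = 1 px)
indicator at level 0.5. The smoothed-contour estimator was chosen after
quantifying the alternatives: naive pixel-edge counting overestimates
smooth perimeters by up to 27%, and a 4-direction Crofton estimate —
Cauchy's projection formula with four directions — underestimates
axis-aligned squares by about 5%; the smoothed contour is within ~1.5%
on discs, squares and equilateral triangles of cell-like size, keeping
the shape index $p/\sqrt{A}$ accurate to the 3% the closed-form checks
demand. The aspect ratio AR = major/minor and shape index SI are
scale-invariant and rotation-tolerant (<2% over orientations); their
population SDs are the shape-variability readouts. Tracked aspect-ratio
series drop detections at or below 10 µm² and are normalized per track
to the first available time point. The cell-cycle reporter ratio is
simply green/(green + red) nuclei.

FRAP movies are quantified with an automatic bleach-region recipe:
median filter (radius 10 px), invert, threshold the inverted image at
65200 counts, keep connected components with area between 2000 and
4500 µm² (the printed range "between 4500 and 2000" is read as
[2000, 4500]), fit the minimal enclosing circle and shrink its *area* by
20% (radius × √0.8) to exclude partially bleached rim cells; multiple
candidate regions are all returned with a supervision flag. Recovery
curves are double-normalized — background-subtracted, divided by a
background-subtracted unbleached reference to cancel acquisition
photobleaching, and scaled to a pre-bleach mean of 1. The default
background is a corner box and the default reference a far-field
annulus (2.5–4 disc radii); both are configurable, and
`background_roi = "none"` disables background subtraction for synthetic
stacks with no cell-free region. `fit_frap_recovery()` fits
$N(t) = p - A e^{-kt}$ post-bleach; with full bleach depth the plateau
equals the mobile fraction. Wetting (spheroid spreading) series are
normalized to the area at time zero.

## The synthetic monolayer generator

The simulator is an overdamped self-propelled-particle model in a
periodic square box: soft repulsive discs (stiffness $k_{rep}$, radius
$a = 5$ µm), self-propulsion $v_0$ along a heading that relaxes toward
the local mean heading within an alignment radius at rate $J$
(continuous-time Vicsek alignment implemented as torque relaxation, so
dynamics remain well-defined at contact) with rotational noise
$\sqrt{2 D_r}$, and an optional harmonic bond network. Units are µm and
hours; positions are sampled every 5 min; both wrapped and unwrapped
coordinates are stored so per-track displacements are exact. With
repulsion and bonds off, the model reduces to a continuous-time Vicsek
model, and the tested noise–order relation (alignment decreasing in
$D_r$, Wilcoxon over 10 seeds at 3 noise levels) confirms that limit.

The four regime presets are documented constants:

| preset | $v_0$ (µm/h) | $J$ (1/h) | $D_r$ (rad²/h) | $k_{rep}$ | bonds |
|---|---|---|---|---|---|
| `jammed_solid` | 0.5 | 1 | 1 | 25 | — |
| `disordered_fluid` | 20 | 0 | 6 | 25 | — |
| `flocking_fluid` | 30 | 10 | 1.5 | 10 | — |
| `flocking_solid` | 20 | 4 | 0.4 | 25 | $k_{bond} = 30$ |

Shared preset constants: packing fraction 0.9 and an alignment radius of
25 µm, about 2.5 cell diameters (at 15 µm counter-propagating domains
can persist for the full run in a minority of seeds, while 25 µm
reliably produces a single flock within a few hours); integration step
1/120 h, reduced to 1/960 h for the bonded preset, whose per-cell
stiffness is the sum over ~6 bonds and needs the smaller step for
stable overdamped integration. The flocking fluid differs from the
solid presets in two physically meaningful ways: softer repulsion
($k_{rep} = 10$ vs 25 — unjamming corresponds to lower effective
cortical stiffness, and at $k_{rep} = 25$ a dense aligned flock is an
*active solid* that exchanges almost no neighbors regardless of its
speed) and stronger heading noise balanced by stronger alignment
($D_r = 1.5$, $J = 10$), which drives the local rearrangements of a
fluid while preserving global order. The bonded preset tethers each
cell to its initial neighbors within 2.6 cell radii — a distance-cutoff
contact network whose topology matches the initial packing — which
suppresses rearrangement while letting the network drift coherently.
Cells start on a jittered triangular lattice, the mechanically stable
packing of soft discs (a square lattice sits on an unstable equilibrium
and buckles during relaxation, confounding relaxation tests).

Default preset size is 400 cells for 12 simulated hours (a ~187 µm box).
These sizes keep a full four-regime, twenty-seed validation sweep within
a routine test run while leaving each run long enough for the flocking
transition to complete and for exchange slopes to be measured over a 2 h
delay range; they are the sizes at which the classifier thresholds were
calibrated, and `make_regime_config()` exposes both knobs.

Seeding: one integer master seed per run; independent sub-streams are
derived for initialization, dynamical noise and rendering, so adding
image rendering to a run does not perturb the trajectories. Identical
configuration and seed give bit-identical tracks.

What the generator does *not* emulate: cell division and extrusion
(density is constant), cell shape (cells are isotropic discs, so the
shape-metrics module is validated on rasterized geometric shapes
instead), signaling gradients, and 3D effects. Passing the closure tests
therefore demonstrates that the measurement chain is correct on motion
of the intended class, not that real tissue obeys this particular
microscopic model.

## The four-state classifier

The state definitions are comparative; the package makes them
operational with explicit thresholds applied in a fixed order:

1. $V_{RMS}$ below `v_rms_low` → **jammed solid** (arrested);
2. otherwise $L_{corr}$ below `l_corr_low` → **unjammed disordered
   fluid**;
3. otherwise exchange slope at or above `exchange_slope_high` →
   **flocking fluid**, else **flocking solid**.

The order parameter is recorded in every call but is not a splitting
criterion — the definitions split on motility, correlation length and
neighbor exchange, and $\psi$ correlates strongly with $L_{corr}$ on
this data. The shape-index SD is carried as a secondary descriptor only,
since shape data may be absent. The numeric thresholds are artifact
constants calibrated once against the simulator presets at the default
study size and shipped as config defaults (`v_rms_low` = 2 µm/h,
`l_corr_low` = 14 µm, `exchange_slope_high` = 0.15 µm/h); on the
calibration sweep the four presets separate by factors of about 1.5–10
on the relevant metric, and 20 seeds per regime classify correctly in
≥ 90% of runs. For experimental data measured with a different window
size or frame interval the thresholds should be re-examined; every call
records the metrics and thresholds it used, so calls are exactly
re-derivable.

When a needed metric is undefined (e.g. the correlation fit did not
converge on a motile tissue) the call is an explicit `"unclassifiable"`
with the reason — never a silent default.

## Pipeline, aggregation and I/O

`run_pipeline()` chains ingest → velocity field (PIV or track
coarse-graining) → kinematics → motility-peak window → correlation fit →
RDF/neighbor exchange → density → shape (if masks are given) →
classification, with per-stage error isolation: a failed or inapplicable
stage marks its section and downstream dependents are skipped, so
partial inputs produce partial reports with explicit gaps. When the
configured framecut lies outside a short series, the last half of the
run is used instead (and recorded in the report). Replicate fields of
view are averaged per time point by `aggregate_replicates()` (nearest
frame matching, mean ± SD with n).

On disk: tracks are CSV (native unit-suffixed columns, or TrackMate
spot exports with header rows skipped by detection); image and mask
stacks are 16-bit multi-page TIFF with a JSON calibration sidecar;
velocity fields use a minimal self-describing binary archive (JSON
header + little-endian doubles) because no community standard exists for
PIV grids; configuration is YAML over documented defaults; reports are
tidy CSV plus JSON summaries and a run manifest. The package's functions
are the interface; the pipeline entry point is `run_pipeline()` and all
stages are callable individually.

## Known limitations

* The PIV is single-pass; strong in-window velocity gradients (shear at
  the scale of one window) bias the peak toward the dominant motion.
* The correlation estimator assumes an (approximately) homogeneous
  field; mixed jammed/flocking regions in one field of view yield an
  averaged $L_{corr}$.
* The exchange statistic requires tracks long enough to span the delay
  range; heavy track fragmentation inflates the dropped-pair count and
  thins the late-delay average.
* Classifier thresholds are calibrated on the simulator's study
  conditions; they are explicit, recorded, and should be revisited for
  imaging setups with very different spatial or temporal sampling.
* The simulator's four regimes are idealizations — constant density,
  isotropic cells, no division — appropriate for validating the
  measurement chain, not for fitting biological mechanism.
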
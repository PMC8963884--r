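---
title: "Morphodynamic maps and the cell-compass model: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphodynamic maps and the cell-compass model: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements:
the measurement side (morphodynamic maps, persistence statistics,
trafficking cross-correlation) and the modeling side (a minimal
stochastic "cell compass" coupling protrusive activity to an internal
polarity axis), together with the numerical choices that were open and
how they were resolved.

## The measurement pipeline

A migrating cell imaged every few minutes yields (i) a closed contour
per frame, (ii) centroids of the cell, nucleus and Golgi complex, and
(iii) optionally a fluorescence channel reporting post-Golgi vesicle
traffic.  From these the package computes:

**Morphodynamic maps** (`build_morphomap()`).  Each contour is forced
counterclockwise and resampled into `n_markers = 100` points
equidistant in arclength (`resample_contour()`), starting from the
vertex nearest the +x direction about the centroid — a fixed,
deterministic convention.  Markers of consecutive frames are paired by
exhaustively testing all `n` circular index shifts and keeping the one
minimizing the total squared distance (`match_contours()`; ties break
towards the smallest absolute, then smallest signed shift).  The map
entry is the distance traveled by each marker per unit time, signed by
the projection of its displacement on the outward normal: positive =
protrusion, negative = retraction.  Speeds are px/frame unless
`pixel_scale` and `dt` are supplied (then length/min).

One numerical subtlety deserves record.  Equidistant-arclength
resampling pins marker positions to the contour's total length, so a
locally growing bump makes all markers downstream of it slide
*tangentially*; with the raw marker-to-marker distance this slip is
booked as spurious ± speed around the entire ring, and maps rebuilt
from a known synthetic movie correlate with the truth at only r ~ 0.78
regardless of amplitude.  The default therefore measures the distance
from each marker to the *nearest point of the next contour* in the
neighborhood of its paired marker, which removes the tangential
component while keeping the sign convention; round-trip correlation
rises to r > 0.95.  The raw variant remains available
(`displacement = "marker"`).

Maps can be recentered per column so that the middle row follows a
reference axis — typically the nucleus-to-Golgi direction
(`recenter_map()`); the applied circular shifts are stored and exactly
invertible (`undo_recenter()`), and recentering never alters a
column's multiset of values.

**Trajectory statistics** (`direction_autocorrelation()`,
`fit_persistence_time()`, `directionality_ratio()`,
`axis_movement_angles()`, `reorientation_series()`,
`cumulative_reorientation()`, `alignment_index()`).  The direction
autocorrelation is `AC(lag) = mean cos(theta(t+lag) - theta(t))` over
step directions; zero-displacement steps yield missing directions
rather than an arbitrary 0° (which would fake alignment).  The
persistence time tau is the decay constant of `exp(-lag/tau)` fitted
by bounded Levenberg–Marquardt over lags up to one third of the track
duration (configurable; the choice is a compromise between resolving
slow decays and not drowning the fit in noise-floor lags).  A curve
that never falls below 1/e in range cannot resolve its own decay: tau
is then reported at the censoring bound (the track duration) and
flagged, rather than extrapolated.  Angle summaries are circular
(mean resultant length r, circular SD `sqrt(-2 log r)`); linear SDs
are also emitted since dispersion conventions differ between
laboratories.

**Trafficking maps** (`build_trafficking_map()`).  Mean fluorescence
intensity is sampled by bilinear interpolation at `ceiling(ray
length)` points along the ray from the Golgi centroid to each contour
marker, excluding samples inside the Golgi mask (the organelle's own
signal would dominate every ray).  Global intensity drift is removed
by matching every frame's mean/SD to frame 1 (`normalize_stack()`);
because the downstream lag estimate is invariant to affine intensity
changes, the difference from histogram-based drift corrections does
not propagate.  `crosscorrelate_maps()` computes, per marker row, the
mean-subtracted normalized cross-covariance versus lag and averages
rows (rows with missing values are dropped, not imputed); the sign
convention is fixed so a *positive* lag means protrusion precedes
trafficking.  `extract_peak_lag()` refines the peak to sub-frame
resolution with a quadratic through the maximum and its neighbors,
flagging maxima at the domain edge.

**Segmentation and tracking** (`segment_object()`,
`track_centroids()`, `correct_stage_jumps()`).  The pipeline order is
fixed: global threshold (Otsu by default, fixed value per channel
optionally), binarize, clear border-touching objects, remove small
objects, morphological closing with a disk (default radius 10 px),
hole filling, one centroid per connected component.  Tracking selects
per frame the candidate centroid nearest the previous selection; gaps
carry the last position forward with a flag.  Stage-following
microscopy introduces jumps equal to stage displacements; the
correction adds back `pixel_scale * (stage(t) - stage(1))`.
Coordinates are 0-based pixel centers, x = column, y = row.

## Synthetic data and what passing tests show

Every stage is tested against generators with known ground truth:
persistent random walks whose heading performs an angular random walk
with increments `Normal(0, sqrt(2 dt / tau))` — chosen because the
direction autocorrelation is then *exactly* `exp(-lag/tau)`, matching
the fitted form; contour movies obtained by explicit-Euler
displacement of markers along current outward normals (valid for
per-frame steps much smaller than the cell radius; self-intersecting
or orientation-flipping evolutions are truncated with a warning);
trafficking stacks whose ray intensities equal the rectified
protrusion map delayed by a known lag (only protrusive values secrete
— retractions produce no signal); and noisy disk images for
segmentation.  These emulate the *statistical structure* the analysis
assumes — not microscopy: no point-spread function, no photon noise
model, single cells only, radially convex trafficking geometry.
Passing tests therefore validate the estimators' correctness and
calibration, not robustness to every real-imaging artifact.

## The compass model

The cell is a ring of `n = 100` markers.  Protrusive events nucleate
with probability `p_nuc = 0.25` per frame (frames are `dt = 5` min).
A nucleated event is placed, with probability `p_polarized`, at
`round(Normal(c_axis, sigma_c = 5))` markers — in front of the
internal polarity axis `c_axis` — and uniformly at random otherwise.
Each event stamps a fixed space–time template onto the morphodynamic
map (events superpose linearly).

**The event template** (`single_event_template()`) is the convolution
(circular in space, causal in time) of a transfer function — edge
motion following a point-like Cdc42 activity pulse — with a signaling
"puff" (spatial Gaussian × exponential temporal decay).  The transfer
function sums four terms: a wide negative spatial Gaussian (initial
lateral inhibition), a narrow positive Gaussian (the protrusion), a
positive Gaussian pair whose centers travel laterally (the wave), and
a negative temporal-Gaussian term at the center (long-lasting central
inhibition).  The template is normalized to total sum zero — constant
cell area — by subtracting its space–time mean, and scaled to peak
speed 1.  Subtracting the mean spreads the compensating retraction
uniformly around the ring, where it carries no net directional motion;
the alternative of rescaling the localized negative lobes in place
leaves each event's retraction co-located with its protrusion, makes
every event's late phase reverse the cell's instantaneous direction,
and destroys persistence in *every* parameter regime — which is why it
was rejected.

The template's amplitudes and widths are free parameters.  They are
pinned by three calibration requirements, all tested: the event
footprint (|speed| above 10% of peak) lasts 10 ± 2 frames (50 min);
the spatial footprint stays below ~20 markers; and each column's
projected centroid displacement is non-negative (a cell on net moves
towards its protrusion).  Defaults: `A1 = 0.35, sigma_wide = 30,
tau1 = 3.5; A2 = 1.5, sigma_narrow = 3, tau2 = 4; A3 = 0.35,
wave_speed = 1.5, tau3 = 4; A4 = 0.2, sigma_mid = 5, tau4 = 6;
sigma_puff = 2, tau_puff = 2` (markers and frames).

**The two-sided feedback.**  Side 1 is the placement bias
`p_polarized` above.  Side 2 moves the axis:

    c_axis(t+1) = c_axis(t) + kappa * g * F_prot(t) + (1 - kappa) * F_basal(t)

`F_prot` sums positive (protrusive) edge speeds, each signed by the
shortest circular direction from the axis to its marker — every
protruding portion pulls with a force proportional to its speed,
independently of distance; retractions do not pull.  The gain `g`
(default 0.8) converts summed speed into markers/frame; it is
calibrated by a pinned-protrusion test: with `kappa = 1` and a single
sustained protrusion, the axis must be captured from the antipode
within one event duration (`axis_convergence_time()`, 11 frames at
default).  `F_basal` is the derivative of the feedback-free axis path:
i.i.d. draws uniform on `(0, 10 n)` smoothed by a moving average
(`natural_axis_path()`); the window (default 36 frames) is calibrated
so the free axis typically sweeps a full turn in ~48 frames (4 h),
the reorientation timescale of unstimulated polarity.

The centroid steps by the marker-velocity mean
`(1/n) sum_i v_i (cos theta_i, sin theta_i)`; trajectories are
analyzed with the *same* code paths as experimental tracks.

**Observables.**  Persistence time tau (exponential fit as above,
censored at the run duration — the "superpersister" corner of the
diagrams is thereby well-defined); protrusive unicity
(`unicity_index()`): the inverse of the mean number of circularly
connected protruding fronts in a sliding 10-frame window, thresholded
at 70% of the maximal protrusion speed; and the alignment index: the
mean resultant length of the angle between axis direction
(`2 pi c_axis / n`) and motion direction, skipping zero-displacement
frames.

The unicity threshold's reference maximum was an open choice: against
the *whole map's* peak, superposition noise means almost no window
shows two fronts and the index saturates near 1 everywhere, washing
out its dependence on `p_polarized`; against *each window's own* peak
(the default), competing fronts are counted on the window's scale and
the index spans ~0.45 (uniform placement) to ~0.9 (fully polarized).
Both are exposed (`threshold_scope`).

**Phase diagrams and inversion.**  `phase_diagram()` runs the
simulation over an 11 × 11 grid of `(p_polarized, kappa)` in [0,1]²
with 20 seeded realizations of 1000 frames per node (seeds derived
deterministically from a base seed, so diagrams are exactly
reproducible) and records mean and SD of the three observables.
`estimate_parameters()` inverts the diagrams for measured observables
by minimizing `sum((sim - measured)/spread)²` on a fine grid.  The
node means are Monte-Carlo estimates, so by default each observable
surface is first fitted with a degree-3 polynomial response surface
(the persistence time on a log scale) — a standard simulation
metamodel that filters node noise; without it, the argmin wanders
along flat parts of the residual landscape from one diagram seed to
the next (observed spread ~0.15 in either parameter across seeds, vs
~0.01 with the response surface; closed-loop recovery is unaffected).
Raw bilinear interpolation remains available (`smooth = "none"`).
The spread defaults to each observable's SD over the whole diagram;
when measurement uncertainties are available they should be passed
explicitly — the acceptance script weights by the measured cohort
spreads.  Missing
alignment (dispersed Golgi) drops that term and flags the fit;
measurements outside the simulated range return the nearest boundary,
flagged as extrapolation.

**Known limitation: a soft inversion ridge.**  The three observable
surfaces all increase with both parameters along broadly similar
gradients, so a measured triple is matched along a soft anti-diagonal
ridge in the `(p_polarized, kappa)` plane — e.g. a moderately
persistent, moderately unipolar, moderately aligned cell is explained
almost equally well by strong placement bias with weak axis coupling
or by moderate bias with strong coupling.  The closed-loop test
(simulate at hidden parameters, re-estimate from the diagrams)
recovers both parameters to within one grid cell, but users should
inspect `estimate_parameters()$surface` (the residual landscape)
rather than trust the point estimate alone, and where possible
constrain additional observables.  In particular, the model's
alignment index saturates around ~0.85–0.9 once `kappa` is large
(axis and motion both lock onto the same polarized event cluster), so
mid-range measured alignments pull estimates towards the low-`kappa`
end of the ridge.

## Problem sizes and reproducibility

Defaults reflect the study conditions: 1000-frame simulations
(83 h at 5 min/frame), 11 × 11 grid, 20 realizations per node — a
full diagram is ~2400 simulations and takes a few minutes on one
core.  Every stochastic component takes a seed; fixed seeds give
bit-identical tracks, maps, simulations and diagrams.
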
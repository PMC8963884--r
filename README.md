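# cellcompass

Quantitative analysis of persistent single-cell migration, and a
minimal stochastic model of why cells migrate persistently at all.

Mesenchymal cells such as RPE1 move by extending protrusions, and
their internal polarity axis — in practice the vector from the nucleus
centroid to the Golgi centroid, along which post-Golgi vesicle traffic
is directed — tends to point where the cell is about to go.  This
package is for researchers who track single cells and their organelles
in time-lapse microscopy and want to (a) quantify edge dynamics and
migration persistence, (b) relate protrusive activity to polarized
trafficking, and (c) interpret those measurements through an explicit
feedback model.

## What it computes

**Measurement side**

- threshold-based segmentation of fluorescently labeled structures and
  nearest-neighbor centroid tracking, with correction of
  stage-following jumps (`segment_object()`, `track_centroids()`,
  `correct_stage_jumps()`);
- morphodynamic maps: 100 markers equidistant along the cell contour,
  paired frame-to-frame by exhaustive circular-shift matching; map
  entry = signed edge speed (protrusion +, retraction −)
  (`build_morphomap()`, `recenter_map()`,
  `mean_protrusion_profile()`);
- trajectory statistics: direction autocorrelation
  `AC(lag) = ⟨cos Δθ⟩`, persistence time τ from an `exp(−lag/τ)` fit,
  directionality ratio, nucleus–Golgi axis vs motion angles,
  reorientation and cumulative-reorientation curves, and the alignment
  index `r = √(⟨sin θ⟩² + ⟨cos θ⟩²)` (`direction_autocorrelation()`,
  `fit_persistence_time()`, `alignment_index()`, ...);
- trafficking maps (mean intensity along Golgi-to-contour rays) and
  their cross-correlation with morphodynamic maps, yielding the
  protrusion-to-secretion time lag at sub-frame resolution
  (`build_trafficking_map()`, `crosscorrelate_maps()`,
  `extract_peak_lag()`).

**Model side — the "cell compass"**

Protrusive events (a calibrated space–time template, zero total sum so
cell area is conserved) nucleate at rate 0.25/frame.  Two feedback
parameters in [0, 1] couple them to a polarity axis `c_axis`:

- `p_polarized`: probability that an event is placed in front of the
  axis (`Normal(c_axis, σ = 5)` markers) rather than uniformly;
- `kappa`: weight of the protrusion pull in the axis update
  `c_axis(t+1) = c_axis(t) + κ·g·F_prot + (1−κ)·F_basal`, where
  `F_prot` sums protrusive speeds signed by their circular direction
  from the axis and `F_basal` is a basal drift that reorients the free
  axis in ~4 h.

`simulate_compass()` returns the synthetic morphodynamic map, the axis
track and the cell trajectory; `phase_diagram()` maps persistence
time, protrusive unicity (1 / mean number of simultaneous protruding
fronts) and alignment over the `(p_polarized, kappa)` plane;
`estimate_parameters()` inverts those look-up tables to estimate the
two feedback strengths from measured observables.

A full synthetic-data module (`gen_prw_trajectory()`,
`gen_contour_movie()`, `gen_trafficking_stack()`, `gen_blob_image()`)
provides seeded ground truth for every stage.

## Worked example

```r
library(cellcompass)

persistent <- simulate_compass(compass_params(p_polarized = 0.8, kappa = 1, seed = 1))
uncoupled  <- simulate_compass(compass_params(p_polarized = 0,   kappa = 0, seed = 1))
for (s in list(persistent, uncoupled)) {
  o <- compass_observables(s)
  cat(sprintf("p_polarized = %.1f, kappa = %.1f -> tau = %.2f h%s, unicity = %.2f, alignment = %.2f\n",
      s$params$p_polarized, s$params$kappa, o$tau / 60,
      if (o$tau_censored) " (censored)" else "", o$unicity, o$alignment))
}

tr  <- gen_prw_trajectory(prw_params(speed = 1, tau = 120, dt = 5, n_frames = 200, seed = 7))
fit <- fit_persistence_time(direction_autocorrelation(tr))
cat(sprintf("PRW with tau = 2 h: fitted tau = %.2f h, directionality ratio = %.2f\n",
    fit$tau / 60, directionality_ratio(tr)))
```

prints

```
p_polarized = 0.8, kappa = 1.0 -> tau = 8.47 h, unicity = 0.80, alignment = 0.96
p_polarized = 0.0, kappa = 0.0 -> tau = 0.44 h, unicity = 0.48, alignment = 0.06
PRW with tau = 2 h: fitted tau = 1.84 h, directionality ratio = 0.21
```

With both feedbacks on, the simulated cell keeps one protrusive front
(unicity 0.80), its axis and motion stay locked (alignment 0.96) and
its direction decorrelates over many hours; with the feedback off, the
same event statistics give an unpolarized, non-persistent cell
(τ ≈ 26 min).  The persistent-random-walk fit recovers the generative
2 h persistence time from a 200-frame track to within sampling error.

`plot(sim$map)` renders a morphodynamic map in the usual red
(protrusion) / blue (retraction) convention;
`plot(pd, "tau", measured = 138)` draws a phase diagram with a
measured iso-contour.

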
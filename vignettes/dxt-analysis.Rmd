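---
title: "Simulating and analysing diffracted X-ray tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing diffracted X-ray tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxtr)
library(dplyr)
```

## The measurement and its model

Diffracted X-ray tracking (DXT) follows the rotational motion of a single
membrane protein by watching the diffraction spot of a gold nanocrystal
(20-60 nm) attached to its surface. With a pink beam (finite bandwidth
$\Delta E/E$), a crystal stays in diffracting condition over a small range of
tilt, and the Au(111) spot it produces moves on the Debye-Scherrer ring as
the crystal reorients. Two angular coordinates describe that motion:

* **tilt** $\theta$, mapped to the radial position of the spot through the
  Bragg condition, and
* **twist** $\chi$, mapped to the azimuth of the spot along the ring.
  Negative $\Delta\chi$ is clockwise (CW) rotation, positive is
  counter-clockwise; this sign convention is preserved through every stage,
  including image rendering and re-detection.

Angles are held in milliradians everywhere; degrees appear only in reporting
(`mrad_to_deg(10.1)` is 0.58°). The default acquisition is 100 µs per frame,
100 frames (10 ms total), a 15 keV beam with 0.02 bandwidth, 50 mm camera
length, and d = 2.355 Å, which puts the ring at 18.41 mm.

## The forward simulator

Because recordings of this kind are rarely deposited, every stage of the
analysis here is exercised against a forward simulator whose structure is the
same one the analysis assumes:

* **Dynamics.** Euler-Maruyama steps per axis: Gaussian increments of
  variance $2D\,\Delta t$ plus $v\,\Delta t$ of drift per frame. Confined
  populations are folded back at a reflecting boundary placed at
  `confinement_radius` on each axis about the track's start. Reflection is
  the simplest mechanism that makes the mean square displacement saturate
  (subdiffusive $\alpha < 1$); per-axis folding (a square region) was chosen
  over radial 2D reflection because the analysis itself treats the axes
  separately.
* **Lifetimes.** Geometric in frames (a memoryless detachment/bleaching
  analogue), truncated to the recording length, never zero frames. The
  default mean is 0.37185 ms: with $q = 3.5^{-1/4}$ the closed form
  $(1-q^4)/(q^4-q^{100}) = 2.5$ fixes the mean at $1/(1-q) = 3.7185$ frames,
  so short-lived tracks (≤ 0.4 ms) outnumber long-lived ones (0.5-10 ms) by
  2.5, the ratio the lifetime filter is built around.
* **Measurement error.** I.i.d. Gaussian noise of s.d. $\beta$ per frame per
  axis, consistent with the $2\beta^2$ intercept of the MSD model below.
* **Seeding.** One master seed; each trajectory draws from its own
  deterministically derived substream, so any subset of track ids is
  reproducible and a fixed seed gives byte-identical tables.

The default two-population mixture (`default_populations()`) is the
"unliganded-like" reference: 67% of tracks fluctuate about their origin
(D = 1.3 mrad²/ms per axis, reflecting radius 4 mrad, so the 1 ms twist
variance is ≈ 2.6 mrad²), and 33% drift clockwise at −10.1 mrad/ms (with a
positive tilt drift), putting their twist-displacement peak at −10.1 mrad
after 1 ms and scaling linearly with lag. The "agonist-like" condition drops
the drifting subpopulation; "inverse-agonist-like" additionally halves the
main population's diffusion. These are named datasets that mirror the
qualitative structure of ligand effects on receptor motion, not a
pharmacological model, and the mixture is a calibration stand-in, not an
inference about mechanism.

What the simulator does **not** emulate: spot-intensity physics (mosaicity,
size broadening, polarization), nonspecific label binding, membrane geometry,
or interactions between molecules. Passing tests therefore demonstrate that
the analysis recovers what the generative model puts in, at realistic sample
sizes and noise - not that any particular biological system behaves this way.

## Rendering and tracking

`render_frames()` draws each live track as a Gaussian spot (default
`psf_sigma` 1.5 px) at the detector position given by the geometry mapping,
attenuated in tilt by a Gaussian acceptance of width
$1000\,\tan\theta_B\,\Delta E/E\,/\,2 \approx 1.8$ mrad - a documented
rendering convenience standing in for the band of tilt angles a pink beam
accepts - plus constant background and Poisson noise, as unsigned 16-bit
counts.

Detection finds 3×3 local maxima above a threshold, suppresses detections
closer than `min_separation` (brighter wins), and refines positions by the
intensity-weighted centroid of a $(2s+1)^2$ window; at high signal-to-noise
this is accurate to well under 0.1 px away from the detector edge. Linking is
greedy nearest-neighbour: candidate pairs within `max_disp` are assigned in
order of increasing distance (ties by track id, then canonical detection
order, which makes the result independent of detection order). There is no
gap closing - a vanished spot ends its track - because track length is then a
physical lifetime, which the lifetime filter interprets. Greedy assignment
rather than global combinatorial optimisation is a documented limitation,
adequate at DXT spot densities where spots sit far apart on the ring.

Two background options exist: a per-pixel temporal median (good when spots
move across many pixels) and a constant. The pipeline's rendered path uses
the constant subtraction, because a temporal median swallows spots that stay
within a pixel - exactly what confined populations do.

## MSD analysis

For each kept track, `time_avg_msd()` computes the temporal MSD
$\delta^2(k) = \langle (x_{i+k} - x_i)^2 \rangle_i$ via an FFT
autocorrelation (algebraically identical to the naive double loop, verified
to 1e-10), and `ensemble_msd()` pools tracks weighting by pair counts, which
equals pooling every squared displacement. The ensemble curve is fitted with

$$\delta^2(t) = D_\alpha t^\alpha + 2\beta^2$$

by weighted Levenberg-Marquardt with bounds $D_\alpha \ge 0$,
$\alpha \in (0, 3]$, $\beta \ge 0$, multi-started at
$\alpha \in \{0.5, 1, 1.5, 2\}$ and selected by residual. The upper bound 3
keeps the optimiser away from ballistic-plus runaways. $\alpha$ classifies
the regime with a ±0.05 band around 1: subdiffusion below, superdiffusion
above (directed motion, e.g. the 1.67-1.74 exponents typical of twisting with
a drifting subpopulation; free 2D Brownian rotation gives a linear curve of
slope $4D$ over both axes). The default fit window is lags up to 25% of the
longest available lag - standard single-particle-tracking practice, since
long-lag MSD points average few pairs and are noisy - and is configurable.

## Displacement distributions, mixtures, maps

Displacements are referenced to each track's first observation ("travel
distance from the original point"); a sliding per-step alternative is exposed
as `displacement_series(origin = "step")`. At a lag that must be an exact
frame multiple (1 ms = 10 frames, 1.6 ms = 16 frames), each qualifying track
contributes one $(\Delta\theta, \Delta\chi)$ pair.

`fit_mixture()` decomposes the $\Delta\chi$ histogram (default 1 mrad bins,
symmetric about 0) into 1-3 Gaussians by weighted least squares on binned
counts (weights $1/\max(\text{count},1)$), matching the histogram-fitting
practice of the field; raw-sample model-based clustering is used only as an
independent cross-check in the tests. Auto selection accepts an extra
component while it cuts the weighted residual by more than half - a
deliberately conservative threshold so that a clean single Gaussian is never
split, while a genuinely bimodal sample (improvement > 90%) always is.
Components are ordered by area fraction; one whose mean lies below
$-2\sigma_{\text{main}}$ is flagged as the fast clockwise subpopulation.
Sample-size floors (50/150/300 values for 1/2/3 components) reject fits that
cannot be stable; identical values are rejected as degenerate.

Two-axis maps bin $(|\Delta\theta|, \Delta\chi)$ on log-spaced tilt and
linear twist edges. $|\Delta\theta|$ (not signed or instantaneous tilt) is
used because the vertical map axis is logarithmic; a floor bin catches
values below the first edge and overflow cells catch the rest, so the map
always sums to exactly 1. Subtraction maps difference two *normalised* maps
- conditions with different track counts stay comparable - and sum to zero
by construction. `timecourse_series()` repeats either summary over increasing
lags with shared binning; for a constant-drift cohort the CW peak moves as
$v\,\Delta t$ (−10.1 mrad at 1 ms, −16.2 mrad at 1.6 ms).

## The pipeline

`run_condition()` chains the stages for one named condition; with
`simulation$render = TRUE` it takes the full image path (render, subtract,
detect, link, invert the geometry) instead of using the simulated angles
directly. All randomness derives from the config seed and the condition name,
so reports are bit-reproducible. The default run simulates 10,000 tracks per
condition: under the calibrated lifetime distribution only ~4% of tracks
survive to the 1 ms lag, so ~400 displacement points remain there - enough
for a two-component fit - while at 1.6 ms only a few dozen survive and the
mixture stage records a skipped fit rather than failing, as a real analysis
with sparse long tracks would. `compare_conditions()` subtracts maps for
every ordered pair (the reverse order is the sign flip) and tabulates deltas
of $\alpha$ and of the main-component variance.

```{r pipeline, eval = FALSE}
cfg <- default_run_config(seed = 1)
reports <- lapply(setNames(nm = cfg$conditions), run_condition, config = cfg)
compare_conditions(reports)
```

## Numerical choices and degenerate inputs

* MSD series are anchored at their first value before the FFT; the MSD is
  shift-invariant, and this keeps constant tracks at exactly zero.
* The pixel-angle mapping and its inverse round-trip to 1e-9 mrad;
  observations at the beam centre (undefined azimuth) are dropped with a
  warning, and off-detector renders are clipped with a warning.
* Absolute twist angles are recovered modulo the full ring; displacement
  analysis is unaffected.
* Histogram grids are aligned to the bin width and symmetric about zero, so
  mirroring a sample mirrors every downstream summary exactly.
* The lifetime filter partitions kept/removed exhaustively and is idempotent;
  a window between `drop_max` and `keep_min` is only reachable on frame grids
  finer than the defaults and is counted separately.

## Problem sizes

The test-suite simulations are sized for routine desk use: 1000 tracks × 100
frames for the Brownian slope check, 10,000 short-lifetime tracks for the
filter-ratio check, 20 replicates of n = 1000 for mixture recovery, a few
hundred tracks for regime classification, and an eight-spot rendered stack
for the end-to-end image path. These sizes hold every check's sampling error
well inside its tolerance; they are stated here as the package's chosen
study conditions.

## Known limitations

* Greedy linking can mis-assign when spot density approaches one spot per
  `max_disp` neighbourhood; DXT ring geometries are far sparser.
* The histogram-least-squares mixture fit inherits binning variance;
  Sheppard-type variance inflation (~bin²/12) is well inside the quoted
  tolerances at the default 1 mrad bins.
* The Ewald-acceptance factor in rendering is a convenience, not a
  diffraction model; rendered intensities should not be interpreted
  physically.
* Conditions are statistical presets; nothing here models ligand binding.
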
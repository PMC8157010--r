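# dxtr

Simulation and trajectory analysis for **diffracted X-ray tracking (DXT)** of
membrane proteins.

DXT watches the diffraction spot of a gold nanocrystal attached to a single
protein: as the protein reorients, the Au(111) spot moves on the
Debye-Scherrer ring. Radial spot motion reports the **tilt** angle θ, azimuthal
motion reports the **twist** angle χ (negative Δχ = clockwise rotation). From
linked spot tracks the method asks: how does the molecule move - freely,
confined, or directed - and does a ligand change that?

`dxtr` implements the full analysis chain and, because beamline recordings of
this kind are rarely public, a forward simulator that generates ground-truth
angular trajectories and rendered diffraction-image stacks so every stage can
be validated against known inputs:

* **simulate** - mixtures of trajectory populations (rotational diffusion
  coefficients `D`, drift velocities, reflecting confinement, geometric track
  lifetimes, measurement noise β), plus 16-bit TIFF image-stack rendering;
* **detect/track** - background subtraction, sub-pixel spot detection,
  greedy nearest-neighbour linking (no gap closing);
* **angles** - exact detector↔(θ, χ) geometry from beam energy, d-spacing
  and camera length (`λ = 12.3984/E`, `sin θ_B = λ/2d`,
  `r = L·tan(2θ_B + 2θ)`);
* **msd** - lifetime filtering (drop ≤ 0.4 ms, keep 0.5-10 ms), FFT
  time-averaged MSD, and the anomalous-diffusion fit
  `δ²(t) = D_α t^α + 2β²` with α < 1 subdiffusion, α ≈ 1 Brownian
  (slope 4D over both axes), α > 1 superdiffusion;
* **popdist** - displacement distributions at exact frame lags, 1-3
  component Gaussian mixture fits on histograms, shoulder-asymmetry
  summaries, normalised two-axis (|Δθ|, Δχ) density maps, and
  condition-vs-condition subtraction maps;
* **pipeline** - seeded, bit-reproducible end-to-end runs over named
  conditions with tidy `tidy()`/`glance()`/`autoplot()` accessors.

## Worked example

Run the reference "unliganded-like" condition - a 67% confined population
plus a 33% clockwise-drifting subpopulation (−10.1 mrad/ms) under the
calibrated short-lifetime distribution - through the whole pipeline:

```r
library(dxtr)
cfg <- default_run_config(seed = 1)
rep_un <- run_condition(cfg, "unliganded")
rep_un
#> <dxt_report> condition unliganded
#>   10000 simulated, 10000 observed tracks, 2854 kept (short:long = 2.50)
#>   theta: alpha = 1.324, D_alpha = 4.52, beta = 0.333 [superdiffusion]
#>   chi: alpha = 1.699, D_alpha = 28.3, beta = 0.212 [superdiffusion]
#>   lag 1 ms: 457 points, 2 mixture component(s)
#>   lag 1.6 ms: 64 points, 1 mixture component(s)

rep_un$per_lag[["lag_1"]]$mixture
#> <mixture_fit> 2 component(s), n = 457, weighted RSS = 7.285
#>      mean variance   sd area_fraction    role
#> 1  0.0801     2.88 1.70          0.73    main
#> 2 -9.8792     2.38 1.54          0.27 fast_cw
```

Reading the numbers: of 10,000 simulated recordings, short-lived tracks
outnumber analysable ones 2.5:1 and are excluded; the twist-axis MSD is
superdiffusive (α = 1.70), the signature of directed motion; and the 1 ms
twist-displacement histogram decomposes into a main population at ≈ 0 mrad
and a clockwise subpopulation peaking near −10 mrad - recovering the drift
velocity × 1 ms put in by the generator. Removing the drifting subpopulation
(`run_condition(cfg, "agonist")`) and subtracting the two conditions' maps
(`compare_conditions()`) leaves all the excess density at Δχ < 0.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/dxt-run.R --seed 1 --out dxt-out
```

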
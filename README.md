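# fibrediff

Time-resolved small-angle X-ray fibre diffraction analysis of contracting
skeletal muscle, in R.

Intact muscle diffracts a synchrotron beam into a highly structured 2D
pattern: equatorial reflections (1,0; 1,1; 2,0) from the transverse
hexagonal lattice of thick and thin filaments, myosin meridionals (M3 at
~14.44 nm, M6 at ~7.23 nm) with interference fine structure from the two
half-filament motor arrays, myosin and actin layer lines (ML1, AL1, AL6)
that report the folded OFF conformation of the motors and their attachment
to actin, and ultra-small-angle sarcomere reflections from the ~2.4 µm
axial repeat. Recording these signals frame by frame during a twitch or
tetanus turns the diffraction pattern into a movie of thick-filament
activation and cross-bridge formation. `fibrediff` implements the full
reduction and analysis chain for such experiments, together with a forward
simulator that renders noisy detector frames from ground-truth structural
time courses, so every stage can be validated end to end without beamline
data.

It is aimed at muscle biophysicists analysing time-resolved fibre
diffraction series, and at method developers who need a reproducible,
fully tested reference pipeline.

## The analysis chain

* **Reduction** — beam-centring and tilt correction from the equatorial
  1,0 pair, quadrant mirroring with dead-tile handling, band integration
  to 1D profiles, and an *arc-hull* baseline: the lower convex hull of the
  (optionally smoothed) profile, subtracted without clipping.
* **Peak decomposition** — constrained multi-Gaussian models:
  * equator: three Gaussians with a single lattice parameter,
    d(1,1) = d(1,0)/√3 and d(2,0) = d(1,0)/2 exactly;
  * M3/M6: low/mid/high-angle interference sub-peaks sharing one axial
    width, plus separately fitted satellites (M3L, M6L, four extra peaks)
    excluded from the totals; total intensity = Σ(component areas) ×
    cross-meridional width; spacing = area-weighted mean of the component
    spacings;
  * AL6: global Gaussian deconvolution against the flanking M7/M8
    meridionals (centres and widths fixed across the series);
  * sarcomere length from single-Gaussian fits of high-order reflections
    via the Bragg relation SL = n/q(n).
* **Calibration** — reciprocal-space scale by linear regression of the
  diffraction orders of a 100 nm etched grating.
* **Time courses** — stimulus-aligned series with the mass-in-beam
  correction (frame-wise division by the relative diffuse background under
  the ML1/AL1 band), rest normalisation, 1:2:1 smoothing, record-level
  quality control and 3-4 frame period averages.
* **Kinetics** — logistic (sigmoid) activation half-times, double-sigmoid
  decompositions for biphasic observables, and linear ("slow") plus
  exponential ("fast") relaxation rate constants.
* **Mechanics** — lattice volume V = (2/√3)·d10²·SL, cross-sectional area
  from wet weight W/(ρ·L·0.69), the per-filament/per-motor force chain,
  and motor-state fractions from the square-of-diffractors rule
  (number fraction = √(relative intensity)).

Everything is tidyverse-native: profiles, time courses and summaries are
tibbles; fitted objects have `tidy()`/`glance()` methods; `autoplot()`
methods plot frames, profiles and time courses.

## Worked example

Per-motor mechanics for a slow muscle developing 110 kPa with 80% of its
cross-section occupied by myofibrils, 1667 nm² of lattice per thick
filament, and 10% of the 294 motors per half-filament attached:

```r
library(fibrediff)
motor_mechanics(stress_kPa = 110, myofibril_fraction = 0.8,
                area_per_filament_nm2 = area_per_filament(38.0),
                motors_per_half_filament = 294,
                attached_fraction = 0.10, strain_nm = 4.5,
                stroke_nm = 6, atp_energy_pN_nm = 100)
#>   myofibrillar_stress_kPa force_per_filament_pN attached_motors
#> 1                   137.5               229.266            29.4
#>   force_per_motor_pN stiffness_pN_per_nm work_per_motor_pN_nm efficiency
#> 1              7.798               1.733               46.789      0.468
```

So the myofibrillar stress is ~138 kPa, each thick filament bears ~230 pN,
~29.4 motors share it (~8 pN each), giving ~1.8 pN/nm motor stiffness,
~48 pN·nm of work per 6 nm stroke and ~48% thermodynamic efficiency
against the 100 pN·nm of an ATP.

If the diffraction signal of the helically ordered OFF motors retains 50%
of its resting intensity at the peak of a tetanus, the fraction of motors
released from the OFF state is

```r
released_fraction(0.5)   # 0.293 -> ~30% released (slow muscle)
released_fraction(0.1)   # 0.684 -> ~70% released (fast muscle)
```

A complete synthetic experiment — simulate, render, reduce, fit:

```r
cfg   <- sim_config("tetanus", seed = 1)
truth <- simulate_timecourse_truth(cfg)
frame <- render_frame(truth, 2, geometry_saxs())    # a resting frame
prof  <- integrate_frame(frame, "radial", c(0, 0.0036),
                         q_range = c(0.012, 0.08))
fit_equatorials(arc_hull_baseline(prof)$profile)
#> <xfd_eqfit> d10 = 39.099 nm, I11/I10 = 0.579 (rms 142)
```

which recovers the configured resting lattice (d10 = 39.10 nm,
I11/I10 = 0.58) from the rendered, Poisson-noisy frame. The whole 64-frame
tetanus series, including sarcomere-length frames, kinetics and the
mass-in-beam correction, runs through `analyse_synthetic_series()` (about
a minute) or `run_pipeline()` for a config-driven run with CSV/JSON
outputs.

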
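---
title: "Models and methods behind fibrediff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fibrediff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fibrediff` analyses time-resolved small-angle X-ray diffraction from
intact skeletal muscle and ships a forward simulator so the whole chain
can be validated without beamline data. This vignette explains the models
the package implements, the choices made where the methodology is
genuinely open, and what the synthetic validation does and does not
demonstrate.

## Reciprocal-space conventions

Reciprocal spacing is q = 1/d (nm⁻¹), not 2π/d, so the third myosin
meridional (M3, d ≈ 14.44 nm) sits in the 0.066–0.072 nm⁻¹ axial window.
The pixel-to-q mapping is linear (small-angle limit); Ewald-sphere
curvature is negligible at the camera lengths this kind of experiment
uses and is not modelled. Detector grids are odd-sized so that a centred
frame has its beam centre exactly on the middle pixel, which makes
quadrant mirroring exact. Ultra-small-angle (sarcomere) work is done in
µm⁻¹.

## The forward simulator

`sim_config()` / `simulate_timecourse_truth()` define per-frame ground
truth for a fixed-end tetanus (64 frames of 10 ms pitch; frame timestamps
are the centres of the 8 ms integration windows; a 237 ms stimulus train
whose last stimulus falls at 234 ms) or a twitch (70 frames of 5 ms
pitch). The default rest and plateau levels, half-times and relaxation
rate constants are the values reported for slow rat soleus muscle at
27–28 °C: force rising with t½ ≈ 72 ms to ~106 kPa; sarcomeres shortening
from 2.43 to 2.15 µm; d(1,0) moving 39.10 → 39.70 nm; S(M3) and S(M6)
moving 14.442 → 14.558 nm and 7.230 → 7.292 nm; the equatorial intensity
ratio rising 0.58 → 1.36; the OFF-state layer-line intensities falling to
roughly half; and biphasic I(M3)/S(M3) with fast (~17–23 ms) falling and
slow (~78–113 ms) rising branches.

Each series is a clamped logistic (zero before the first stimulus,
renormalised so the plateau is exact), or a sum of two opposite-sign
clamped logistics for the biphasic observables. Relaxation multiplies the
deviation from rest by a linear-then-exponential envelope: unity until the
first frame after the last stimulus (244 ms), a linear decay at the
configured slow rate to 344 ms, then an exponential decay at the fast
rate. The twitch uses a falling logistic instead. These closed forms are
exposed by `truth_series()` so tests can evaluate densely sampled oracles
(half-maximum crossings, biphasic minima) independently of the pipeline.

`render_frame()` turns a truth frame into expected counts: a diffuse
double-exponential background in |q| with a single axial anisotropy
factor, plus separable 2D Gaussians for every reflection, placed
four-quadrant symmetrically at (±radial position, ±1/axial spacing), with
a mass-in-beam factor scaling *everything* (reflections as well as
background — extra tissue in the beam diffracts more in every feature).
Observed counts are Poisson draws from a per-frame substream derived
deterministically from the master seed, so rendering is bit-reproducible.
Interference fine structure is *empirical*: M3 is rendered as LA/MA/HA
sub-peaks at spacing offsets +0.25/0/−0.22 nm with area fractions
0.21/0.55/0.24 chosen so the area-weighted mean equals the configured
S(M3) exactly (M6 analogously with ±0.06 nm offsets); no helical-transform
physics is attempted, and the sampled layer-line spot amplitudes are set
so that at rest I(1,1,1) > I(1,0,1), I(1,1,2) > I(1,0,2) and
I(1,0,3) > I(1,1,3), reproducing the qualitative sampling pattern of a
simple-lattice slow muscle. The diffuse-background functional form and
the absolute count scale are simulator choices (nothing in the
experimental method pins them down); amplitudes were set once to give
bright equatorials (~10⁵ counts), meridional clusters of a few ×10⁴
counts and weaker layer lines, i.e. the regime of frames averaged over a
handful of tetani.

## Reduction

Centring fits the ±1,0 equatorial reflections (Gaussian centres in both
detector directions); the beam centre is their midpoint and the tilt is
the angle of the line joining them. The frame is then resampled
(bilinear, in reciprocal space) so the centre lands exactly on the middle
pixel and the equator is horizontal, with a second estimation pass to
confirm convergence; masked pixels propagate as masked. If one 1,0
reflection is hidden by a dead tile, the 1,1 reflection on that side
substitutes, using the hexagonal √3 ratio of their radii. Mirroring
averages selected quadrants with mask-aware weight renormalisation.
Integration sums counts across a transverse band per longitudinal bin,
rescaling each bin by the fraction of unmasked band pixels, and
propagates Poisson variance.

The *arc-hull* baseline is defined here as the lower convex hull of the
boxcar-smoothed profile (half-width 2 bins by default), linearly
interpolated between hull vertices, with a `depth` parameter that can push
the hull below the data by multiples of the local noise scale (depth 0 by
default). Negative residuals are kept so band integrals stay unbiased.
The name describes its behaviour — a baseline strung under the arcs of
the profile; the underlying commercial implementation it mimics is not
publicly specified, so the convex hull was chosen as the deterministic,
testable definition.

## Peak models

* **Equator**: three Gaussians with a single free lattice spacing —
  centres 1/d, √3/d, 2/d — free widths and amplitudes, fitted over
  0.02–0.065 nm⁻¹ by bounded Levenberg–Marquardt. The weak ~0.04 nm⁻¹
  Z-disc reflection of fast muscle is not modelled (absent in slow
  muscle). Intensity is Gaussian *area*, never height: the sum rule
  (total = Σ areas × radial width) and the width correction are only
  meaningful for areas. A fitted d(1,0) outside 30–50 nm is an error.
* **M3/M6 clusters**: LA/MA/HA share one width and are parameterised as
  the MA centre plus two positive separations bounded in
  [5×10⁻⁴, 1.8×10⁻³] nm⁻¹, which preserves the interference structure and
  enforces the minimum component separation. The satellites — M3L
  (~15.52 nm), M6L (~7.62 nm) and four extra peaks in 0.062–0.067 nm⁻¹ —
  are fitted with their own/equal widths and excluded from the totals.
  When the LA amplitude pins at zero (typical at rest) the model drops LA
  and refits. In time-series use the fit is warm-started from the
  previous frame and the satellites are frozen at their rest-frame
  parameters (`freeze_satellites = TRUE`): during activation the LA
  sub-peak approaches the fourth extra peak to within about one width,
  and free per-frame fits can swap them on unlucky noise draws; the
  satellites do not change during contraction, so fixing them from the
  well-separated rest frame removes the degeneracy — the same logic as
  the global AL6 deconvolution below.
* **Cross-meridional width**: two concentric Gaussians plus an affine
  background fitted to the raw radial profile of the reflection's axial
  band; the narrower width is returned (components carrying <2% of the
  area are ignored as noise spikes; if both widths agree within 5% the
  mean is returned with a warning). Totals are multiplied by this width
  to correct for lateral misalignment between filaments.
* **AL6**: the 0.166–0.178 nm⁻¹ axial window overlaps the M7/M8 tails, so
  three Gaussians are fitted globally on the series mean (centres and
  widths frozen) and per-frame amplitudes recovered linearly; components
  whose global amplitude collapses are dropped before the linear stage. A
  narrow-window mode integrates 0.166–0.170 nm⁻¹ only.
* **Sarcomere length**: single-Gaussian fits of a stated order n in its
  window; SL = n/q(n). The expected position comes from a prior SL
  estimate — in series analysis the previous frame's SL, since sarcomeres
  shorten by >10% during force development — and a competing population
  inside the window flags the fit low-confidence (during relaxation,
  multiple sarcomere populations genuinely preclude assignment).

## Time courses, kinetics, mechanics

Intensity columns (names starting `I_`) are divided frame-wise by the
relative diffuse background under the ML1/AL1 band (the hull-baseline
integral of that profile) and then by their mean over all pre-stimulus
frames. The correction is skipped, and the decision recorded, when the
background never deviates by ≥1% (the twitch case). The equatorial ratio
is exempt from both: it is reported absolute, and frame-wise scalings
cancel in a ratio. Period summaries average 3–4 frames per period, with
"mechanically relaxed" defined as the first frames after force falls
below 5% of its peak above rest (no numeric threshold exists in the
methodology this reproduces; 5% is this package's choice). Amplitudes are
A = √I per record — diffracted intensity scales with the square of the
number of coherent diffractors — and averaging √I across records before
squaring never exceeds averaging I (Jensen), which the tests assert on
simulated ensembles.

Kinetics use a logistic y₀ + a/(1 + exp(−(t − t½)/τ)) — "sigmoidal" does
not pin down a formula, and the symmetric two-shape logistic with a
baseline offset is the minimal choice; the fitted t½ is reported relative
to the first stimulus (activation), the last stimulus (tetanus
relaxation) or t = 52.25 ms (twitch relaxation). Biphasic observables get
a sum of two opposite-sign logistics with the branch order enforced by a
positive-gap parameterisation (≥20 ms at initialisation). The slow
(isometric) relaxation rate is −slope/(value(244 ms) − rest) from a
linear fit over 244–324 ms, in s⁻¹; the fast rate is a single-exponential
fit over 344–604 ms.

The mechanics module is exact arithmetic: CSA = W/(ρ·L·0.69) with unit
bookkeeping to mm²; lattice volume V = (2/√3)·d10²·SL; area per thick
filament (2/√3)·d10²; the stress → per-filament force → per-motor force →
stiffness → work → efficiency chain with 1 kPa × nm² = 10⁻³ pN exactly;
and motor-state fractions 1 − √I (released) and √I (attached) from the
square-of-diffractors rule. Defaults: 294 motors per half-filament,
100 pN·nm per ATP, both configurable.

## Validation strategy and its limits

The test suite validates every closed-form operation against independent
oracles (hand arithmetic, dense-grid evaluation of the generator's closed
forms, shifted-regression identities) and asserts the structural
invariants: exact lattice constraints, the sum rule, baseline ≤ smoothed
profile, mirroring idempotence, Bragg round trips, the dimensional audit
(138 kPa × 1667 nm² = 230.0 pN) and released ∘ (1−x)² = x.

The end-to-end test renders a full 64-frame synthetic tetanus (with
beam-centre offset and 0.3° tilt), runs the complete pipeline, and
requires: d(1,0) within 0.1% and S(M3)/S(M6) within 0.02/0.01 nm on every
frame; sarcomere length within 0.2%; the normalised cluster and
deconvolution intensities (I(M3), I(M6), I(AL6)) and the equatorial ratio
within 5% of truth as 3-frame period averages (the reporting unit of this
kind of experiment); activation half-times within one frame pitch,
double-sigmoid branches within 15%, and relaxation rate constants within
10%, in each case comparing the estimator on measured data against the
same estimator on the noiseless truth series. The run takes about a
minute on one CPU; problem sizes (1601×701 px small-angle frames,
4001×151 px sarcomere frames) were chosen as the smallest grids that
resolve the M3 fine structure and the 14th–24th sarcomere orders.

Two caveats matter when extrapolating to real data. First, the
band-integral observables (I(ML1), I(1,0,1), I(1,1,1+2,0,1)) measure
*blends*: the simulator deliberately overlaps the sampled spots with the
diffuse first layer line and AL1, as in a simple-lattice slow muscle, so
the configured spot amplitudes are not individually recoverable from band
integrals even in principle. These observables are therefore validated
against the same pipeline run on noise-free renderings (within 10% as
period averages for I(ML1) and I(1,1,1+2,0,1)), and for the 1,0-column
band — which sits on the steep shoulder of the diffuse layer line, where
the convex-hull baseline's small noise-induced downward bias is amplified
— the assertion is time-course agreement (half-time within one frame
pitch of the noise-free reference) rather than absolute level. Hull
baselines under noise are biased low by roughly the smoothed noise
amplitude, inflating small band integrals by several percent; real
analyses mitigate this by averaging many contractions, exactly as the
simulator's high-count regime emulates. Second, the simulator's
trajectories are the smooth closed forms above: passing tests demonstrate
that the pipeline faithfully recovers what the generator encodes at
realistic counting statistics, not that real muscle follows those forms.

Out of scope by design: physical helical-transform modelling of the
myosin lattice, polarisation/absorption/point-spread corrections,
flat-fielding and dezingering, absolute wavelength determination, and the
structural model mapping AL1 intensity to absolute attached fractions.
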
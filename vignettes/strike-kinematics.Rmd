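---
title: "Marker-based suction-strike kinematics: models, parameters and numerical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based suction-strike kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strikekin)
```

## The measurement problem

Biplanar videoradiography with implanted radio-opaque beads yields 3D
trajectories of markers fixed in individual skull bones, typically at 150 or
500 frames s⁻¹ with per-coordinate tracking noise on the order of
0.03 cm. From these, a feeding-mechanics analysis needs: rigid-body poses per
bone; joint rotations in anatomically meaningful axes; oral-cavity volume
over time; the share of volume change attributable to each bone (RCVC);
muscle length changes; and prey motion. `strikekin` implements that chain,
and — because in-vivo recordings have no ground truth — ships a synthetic
generator whose output has exact known poses, so every stage is validated by
round-trip recovery.

## Rigid bodies and filtering

Poses are fitted per frame by the weighted Kabsch/Umeyama algorithm: the
proper rotation and translation minimizing the weighted sum of squared
marker distances, via SVD of the cross-covariance, with the smallest
singular direction flipped if the best orthogonal map is improper — a
reflection is never returned. Frames with fewer than three visible,
non-collinear points are flagged invalid and never interpolated; downstream
operations propagate validity. Virtual constraint points (e.g. at a
symphysis or a joint) enter the fit at configurable weights (default 1,
equal to real markers; the weighting is not standardized in practice, so it
is exposed as configuration).

Filtering is a 4th-order low-pass Butterworth (bilinear-transform design)
run forward and backward, so the net response is zero-phase with squared
magnitude — event timings are not skewed. Series are extended by odd
reflection and the filter state is initialized at its DC steady state, so
constants pass through exactly and edge transients are suppressed. The
default cutoff is 35 Hz, the conventional choice for feeding strikes lasting
hundreds of ms. The order, padding, and whether filtering acts on marker
coordinates (then refit) or on pose channels are not fixed by convention;
this package defaults to marker-level filtering followed by refitting, and
both routes are available.

Noisy markers can additionally be refined with a sliding-window least-squares
polynomial (Savitzky–Golay-style; one-sided shrunken windows at the ends).
This mirrors the common treatment of hyoid markers, whose long-axis rotation
is geometrically noise-amplified (see *Noise budget* below).

## Joint coordinate systems

Each JCS pairs an anatomical coordinate system (ACS) fixed in a proximal
bone with one in a distal bone. Per frame the relative transform
`(P·ACSp)⁻¹·(D·ACSd)` is decomposed in **intrinsic zyx order** (right-hand
rule): `R = Rz(rz)·Ry(ry)·Rx(rx)`, rotations reported in degrees,
translations along the proximal ACS axes. The default placements follow
standard practice for this system: jaw JCS at the jaw joint with z
mediolateral (rz < 0 = depression); ceratohyal JCS at the posterior end of
the bone with x along the long axis and z roughly in the frontal plane ~30°
off sagittal (rz < 0 = depression, rx < 0 = internal long-axis rotation);
neurocranium vs the body plane with z mediolateral (rz > 0 = elevation);
clavicle and cranial-rib z along their retraction ("bucket-handle") axes.
Exact numeric placements are rig configuration, not code.

Near gimbal lock (|cos ry| < 10⁻⁶) the convention is fixed and flagged: rx
is set to 0 and rz absorbs the observable combination; recomposition still
reproduces the rotation matrix. ry never approaches ±90° in realistic
strikes. Channels are zeroed by subtracting their value at a reference frame
("start of the strike"). With noisy data the reference frame's own noise is
injected into every reported magnitude, so the canonical pipeline zeroes at
a frame ~50 ms before the detected onset, inside the quiet pre-roll — the
value there is identically zero in the noiseless world and minimally noisy
otherwise.

## Endocast and alpha-shape volumetry

Oral-cavity volume is measured from locators attached to the bones bounding
the right anterior half of the cavity (palate, mouth floor, medial
ceratohyal face, anterior clavicle face, midline wall — 43 locators in the
default definition). Per frame the locators are mapped to world space and an
**alpha shape** is computed: the union of Delaunay tetrahedra whose
circumradius is at most `alpha`. We interpret `alpha` as a circumradius
threshold in cm (toolbox conventions differ — some use 1/radius; ours is
documented and configurable), default 2. The unilateral volume is doubled
(bilateral factor 2, configurable). As `alpha → ∞` the measure converges to
the convex hull volume; small alphas capture concavity. Disconnected
components all count toward the total (configurable in principle; the
default definition never fragments at alpha = 2).

The Delaunay tetrahedralization is an in-package incremental Bowyer–Watson
implementation (no suitable dependency exists in this environment). Two
numerical points matter:

* **Degeneracy.** Structured clouds (grids, coplanar rings) are exactly
  cospherical; a tiny deterministic jitter (10⁻⁸ of the cloud extent, from a
  nonlinear hash so structured inputs do not stay structured) makes the
  triangulation unique without touching R's RNG or the volume at any
  meaningful precision.
* **Predicate robustness.** The in-sphere test decides correctness. The fast
  path compares squared distances against precomputed circumspheres with a
  condition-aware error band (the Cramer-rule numerators' magnitudes
  amplified by 1/det); marginal or degenerate cases fall through to a
  compensated double-double determinant predicate (~32 significant digits).
  This reproduces reference triangulations exactly on random clouds and
  measures an 11×11×11 unit-cube grid at 1.000 cm³.

## RCVC

Over each rolling window `[t, t+N]` (step 1 frame, value timestamped at the
window centre, truncated end windows dropped for constant-N comparability),
each freeze unit's pose relative to the neurocranium is held at its frame-`t`
value — the freeze holds the start-of-window pose, the definition all oracle
tests are written against — and the volume change is remeasured:

`RCVC_i = (ΔV_full − ΔV_frozen,i) / Σ_j |ΔV_full − ΔV_frozen,j|`

Bilateral ceratohyals and clavicles are frozen as mirrored pairs by default
(per-side freezing via `per_side = TRUE`); the cranial rib is excluded from
the default freeze units because it does not bound the oral cavity. Windows
where no unit affects the volume (zero denominator) are flagged degenerate
and report 0. Default windows: 20 frames (40 ms) at 500 fps, 12 frames at
150 fps, ~40 ms otherwise.

## Events, summaries, regression

Gape is operationalized as the 3D distance between anterior upper- and
lower-jaw landmarks (no standard operational definition exists; this one is
recorded in outputs). Onset is the last frame before the gape excursion
exceeds a threshold fraction (default 5%) of its peak above the first-frame
baseline; jaw close is the first frame after peak gape back below that
level; peaks take the first frame attaining the extremum (tie-break rule).
Note a C¹ (raised-cosine) onset crosses a 5% threshold ~40 ms after motion
mathematically begins; on noiseless synthetic data a much smaller threshold
recovers the generated onset to within a frame, which is what the acceptance
checks use. `peak_value()` optionally fits a local quadratic around the
extremum — an unbiased, low-variance peak estimator for smooth noisy
channels (plain extrema of noisy series are biased outward by roughly 1–2
standard deviations of the filtered noise).

Trials are aligned at peak gape (t = 0) and averaged with per-time-point
trial counts; s.e.m. = sd/√n, NA where n = 1. The interspecies comparison is
an ordinary least-squares regression of time to peak gape (ms) on body
length (mm) — `stats::lm` behind a validated interface.

## The synthetic world

The generator is a forward-kinematics model, not a hydrodynamic one. Bodies
move by **raised-cosine** profiles (0 → amplitude over `time_to_peak`, back
over `return`; C¹ everywhere) — the functional form is a convenience; only
peaks and timings carry information. Defaults are the mean in-vivo strike
kinematics: jaw −11.6° peaking 273.1 ms after onset (duration 465.6 ms),
cranial elevation +3.8° (peak +47 ms re peak gape), ceratohyal depression
−20.7° (+94.2 ms), long-axis rotation −13.3° (+151.4 ms, composed
depression-then-long-axis about the bone's own axes; the true coupling law
is unknown), clavicle −22.4°, cranial rib −7.7°, all with a 150 ms quiet
pre-roll in an 850 ms trial. The prey starts 2 cm rostral of the jaws and
follows a constant-acceleration (2432.7 cm s⁻²) burst to 63.3 cm s⁻¹ near
peak gape, then exponential velocity decay sized to a 4.9 cm total path.
Tongue markers ride the ceratohyal tips with a 7% stretch factor scaling
their triangle at peak depression. Marker noise is i.i.d. isotropic Gaussian,
default σ = 0.029 cm (the reported tracking precision); identical seeds give
bit-identical output, with the global RNG state restored.

What the generator does **not** emulate: soft-body tongue deformation, water
flow and prey–flow coupling, marker occlusion/tracking failures, skeletal
deformation of the "body plane" (it is generated rigid; the residual column
of `fit_body_plane()` is the deformation diagnostic on real data), and
non-stationary noise. A green round-trip test therefore establishes that the
*analysis chain* is correct and noise-calibrated — not that the biological
assumptions of any particular study hold.

Marker placements in the default rig spread across each bone (tooth plates
span ~3–4 cm; ceratohyal markers sit at ±1.1 cm radial offsets on a deep
hyoid bar). Lever arms set angular precision: with σ = 0.029 cm,
single-frame JCS noise is ~0.6–1° for hinge channels but ~2° for ceratohyal
long-axis rotation, which only radial offsets constrain — the same geometry
that makes real long-axis channels the noisiest. After 35 Hz filtering,
polynomial refinement of the ceratohyal markers (window 81 frames = 162 ms,
order 2 — bias < 0.1° on 300 ms raised-cosine motions), pre-onset zeroing
and quadratic peak fitting, per-channel peak recovery errors have
sd ≈ 0.2–0.5°; across random seeds the long-axis channel occasionally still
exceeds 1° — an honest floor set by bead geometry, matching the in-vivo
experience that long-axis rotation is the hardest DOF.

## Numerical choices, in one place

* Rigid fit: SVD Kabsch; reflection guard; weighted; collinear sets rejected.
* Butterworth: order 4 per pass, forward–backward, odd-reflection padding,
  DC-exact state initialization; cutoff must be below Nyquist.
* Derivatives: second-order central differences, one-sided second-order
  stencils at the ends (exact on quadratics; the acceleration stencil is
  exact on cubics in the interior).
* Euler: intrinsic zyx; gimbal convention rx = 0 / flagged at
  |cos ry| < 10⁻⁶.
* Alpha shape: circumradius convention; deterministic 10⁻⁸ jitter;
  double-double in-sphere fallback; degenerate coplanar clouds return 0 with
  a warning.
* RCVC: start-of-window freeze; step 1; centre timestamps; end windows
  dropped; zero denominators flagged.
* Events: 5% default threshold (configurable in (0, 0.5)); first-frame
  tie-breaks; peak times reported in ms relative to peak gape, negative
  before.

## Known limitations

* No marker tracking, camera models or distortion correction — input is
  tracked 3D points.
* No gap filling; bodies are lost for frames with fewer than three visible
  markers.
* The alpha-shape implementation targets locator-scale clouds (tens to ~10³
  points per frame); it is pure R and not built for 10⁵-point meshes.
* Helical-axis decomposition, inverse dynamics and EMG are out of scope.
* The synthetic prey law is kinematic: it does not enforce consistency
  between buccal expansion rate and prey acceleration.
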
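---
title: "Methods: real-time dose reconstruction and coverage forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: real-time dose reconstruction and coverage forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `rtdose`, in the spirit of a methods section: what is computed, under
which assumptions, and what the synthetic studies do and do not demonstrate.

## The workflow

During an MR-guided treatment the linac emits state messages at 5 Hz
(timestamps, jaw/MLC positions, gantry angle, cumulative MU, beam state)
while the MR side supplies either rigid target translations at 5 Hz or 3D
images every imaging window (default 10 s, matching a ~10 s dynamic scan).
Between two consecutive control points with the beam on and ΔMU > 0, a
*beam segment* is created; its aperture is held at the start control point
(step-and-shoot assumption — plans whose aperture moves within a segment,
as in VMAT, are out of scope). Three dose distributions are maintained:

* **delivered** — per-segment dose on the instantaneous anatomy, mapped to
  the reference frame and accumulated with an MU ledger;
* **planned-to-same-MU** — the plan truncated at the delivered MU on the
  unmoved anatomy (noise-free), with the straddled plan segment scaled
  linearly in MU;
* **forecast** — delivered + remainder of the plan on the latest frozen
  anatomy, summarized as CTV V95%.

## Dose engine

The engine is an analytic primary-beam model, deliberately simple and
pluggable (any dose engine exposing "dose of one aperture/ΔMU on one
density grid" can replace it):

$$D(v) = \Delta MU \cdot O \cdot F(u, v) \cdot (SAD/r)^2
  \cdot e^{-\mu\, d_{rad}(v)}$$

| parameter | default | meaning |
|---|---|---|
| `sad_mm` | 1435 | source–axis distance (MR-linac geometry) |
| `mu_water_per_cm` | 0.05 /cm | effective attenuation of a ~7 MV beam in water |
| `penumbra_sigma_mm` | 5 | Gaussian penumbra at isocenter |
| `output_gy_per_mu` | 0.016 | Gy/MU at zero depth on-axis (≈1 cGy/MU at 10 cm water) |
| `noise_rel_sd` | 0.05 | per-voxel relative SD per calculation |

Radiological depth is an exact Siddon traversal of the voxel-constant
density grid (mm · g/cm³ → g/cm², i.e. cm water-equivalent). Aperture
fluence treats the MLC opening as a union of per-leaf rectangles clipped by
the jaws; because the rectangles are disjoint along the leaf-stacking axis,
the Gaussian penumbra convolution factorizes exactly into products of edge
CDFs — the fluence at a long straight edge is exactly 0.5. Leaves more than
6.5 σ away along v, and voxels projecting more than 5 σ outside the
aperture bounding box, are skipped; the truncated contributions are below
10⁻⁷ of an open field and the same rule applies to every code path, so
identities between delivered and planned doses are preserved bit-for-bit.

The noise term multiplies each voxel by $1+\varepsilon$,
$\varepsilon \sim N(0, \sigma_{rel})$ i.i.d. per voxel per calculation,
quoted at voxels above 50 % of the segment maximum (a common Monte Carlo
convention; the reference region is our declaration, not something the
workflow defines). Accumulating $n$ equal segments scales the relative SD
as $1/\sqrt{n}$ (`combined_uncertainty`), which is both asserted
analytically and recovered empirically in the test suite. Planned doses and
forecast remainders are computed noise-free: they stand for the plan's
lower-uncertainty offline calculation, and emulating a second noise level
would add nothing testable.

Engine calibration: `calibrate_output()` rescales the output factor so the
planned CTV mean equals 102 % of the prescription — ordinary plan
normalization, which puts the 95 % isodose just outside the target so the
planned V95 is 100 %.

## Geometry and frames

Axes are (x = LR, y = AP, z = CC) in mm with the isocenter at the origin;
the gantry rotates about z, with the source at $+y$ for gantry 0. The
beam's-eye-view axes are u (leaf travel) and v (leaf stacking ≡ z).

**Rigid states.** Computing the dose on an anatomy translated by $t$ and
resampling it back by $-t$ is *analytically identical* to computing the
dose with the whole beam geometry (source, isocenter, aperture projection)
shifted by $-t$. The implementation uses the joint form, which avoids two
trilinear resamplings per segment and keeps the static scenario an exact
identity (delivered ≡ planned to ~10⁻¹⁴ Gy). The virtual diode measurement
uses the same rest-frame equivalence — it *is* the physics of a detector
riding on the motion platform.

**Deformable states.** A displacement field $u$ is used in the pull-back
sense: `warp(v, u)(x) = v(x + u(x))` produces the current image from the
reference. Segment dose is computed on the warped density and mapped back
through the fixed-point inverse of $u$; a constant field therefore inverts
exactly to its negation, and the composition residual on generator fields
stays below 0.1 voxel (tested). The direction convention is a declaration —
the workflow only needs one consistent choice plus an inverse.

## Registration stand-in

The production workflow would use a dedicated (multi-modal) DIR algorithm;
here a mono-modal, multi-resolution, diffusion-regularized demons registrar
stands in, and externally supplied DVFs are accepted everywhere. Per
iteration: warp moving by the current field, intensity-driven update
$-\,\delta \nabla w / (|\nabla w|^2 + (\delta/\kappa)^2)$ capped at 0.8
voxel, Gaussian smoothing (σ = 3 mm) of the accumulated field. Levels
coarsen by powers of two; each level keeps the best field so far and stops
after 8 iterations without MSE improvement, so the reported residual trace
is non-increasing by construction. Two guards are applied to the output:
the field is tapered to zero over a 4-voxel boundary margin (air carries no
registration signal, and an unconstrained boundary can produce spurious
displacements that break invertibility), and it is re-smoothed until the
largest neighbour difference of any component is below 0.9× the voxel
spacing — a sufficient condition for a non-folding, invertible field.

Intensity demons can only recover displacement where intensity gradients
exist; in flat regions the field is filled in by regularization. The
translation-recovery test therefore uses a textured volume (as real MR
images are), and the ridge-recovery test evaluates the error in the
film-plane region, where the water/slab interface provides contrast. This
is a genuine limitation the stand-in shares with its clinical counterparts.

## Synthetic phantoms and the measurement oracle

`build_phantom()` provides three setups (densities: water 1.0, slab 1.02,
air 0.0012, marker 1.1 g/cm³; all on 64³ × 3 mm grids by default):

* `water_cylinder` — homogeneous sanity phantom;
* `delta4_like` — a water cylinder (radius 90 mm) with point diodes on two
  orthogonal interior planes (5 mm pitch, ±50 mm, 40 Hz readout) and a
  25 mm-radius spherical CTV at the isocenter;
* `waterbag_film` — water over a water-equivalent slab with a 5 × 10 cm
  virtual film at the interface (2 mm pixels) and two fiducial marker
  voxels at the film ends, plus an MR-like intensity channel.

The *measurement* is the same analytic engine run noise-free on the
ground-truth anatomy, evaluated exactly at the (moving) detector positions
— diodes at the segment-midpoint motion interpolated from the true trace,
film at the pulled-back film positions per deformation phase. This
separates the delivery simulation (ground truth) from the pipeline under
test (5 Hz nearest-sample sync, segmentation, reconstruction, noise,
accumulation, forecasting): a static run must agree identically, while any
sync/reconstruction defect shows up as σ_C above the noise floor. What
passing these studies does *not* show: detector physics (diode response,
film LUTs), MR contrast/acquisition effects, multi-modal registration, or
magnetic-field dose effects — none are modeled.

Motion traces: `static`, `linear_drift` (CC 0 → 10 mm by default), and
`patient_like`, a piecewise-linear rise-to-apex with partial return
(apex 8 mm, return to 2 mm) standing in for a measured prostate drift whose
values are not tabulated anywhere re-usable. The deformable scenario pauses
the beam twice (3 s holds) and switches the true anatomy to a Gaussian
ridge (`roll_dvf`, crest displacement 14 mm, 1/e half-width 15 mm, crests
at z = ±25 mm) — a virtual wooden roll pushed under the bag. The amplitude
and width were chosen once so that the induced film-dose change (a few
percent, via the shortened radiological path and inverse-square gain) is
clearly detectable by a 2 %/2 mm gamma test, as the physical roll's effect
was; the deformation stays comfortably below the folding limit
(max |∇u| ≈ 0.8).

The plan generator produces step-and-shoot segments at evenly spread
gantry angles with per-leaf jittered field edges and randomized MU weights
normalized to the exact total (defaults: 9 segments, 80 MU each, 8 cm
field across the leaves, 7 cm along CC leaving a 10 mm margin around the
CTV — a realistic prostate-like margin that makes coverage genuinely
sensitive to a 10 mm drift). The stream generator delivers MU at a
constant rate while the beam is on, inserts a 0.4 s hold at plan-segment
changeovers (MLC repositioning), and clamps MU at segment boundaries so
every control-point pair lies within one plan segment — without this, a
straddling pair would mix two apertures and the static identity between
delivered and planned dose could not hold exactly. All generators are
deterministic under a seed (same-seed plans serialize byte-identically).

## Metrics

* **Deviation series** — at each evaluation point, σ (sample SD, n−1
  denominator; the workflow does not define which estimator, so ours is
  declared and tested) and mean absolute difference of cumulative
  measured−planned and measured−calculated doses, over diodes whose planned
  dose lies in the inclusive 60–85 % band of the planned maximum (the
  high-gradient diodes most sensitive to motion). Both statistics are kept
  because a constant offset is invisible to σ but not to the MAD.
  Deviations are evaluated by exact point evaluation at the diode
  positions on both sides, mirroring a physical array compared against
  dose sampled at its diode locations.
* **V95** — percentage of CTV voxels at or above 95 % of the
  *prescription* (not of the maximum dose; the clinical convention).
  Rigid sessions evaluate the planning CTV: under the frame handling
  above, dose and target are expressed in the same reference frame.
* **Gamma** — global normalization by the reference maximum, 2 %/2 mm,
  5 % low-dose threshold on the reference. The search is exhaustive over a
  ball of radius 3×DTA on a sub-voxel lattice (DTA/10 steps) with trilinear
  interpolation, visiting candidates in order of increasing distance so the
  scan stops once the spatial term alone exceeds the current minimum —
  this early termination is exact, and the test suite keeps an independent
  brute-force search that must agree to 10⁻⁶. A pass is γ ≤ 1 with 10⁻⁹
  slack so that a deviation exactly at the criterion passes.

## Timing model

Wall-clock stage costs are simulated constants (defaults: 82 ms per
segment dose, 3 s per DIR, 3 s per engine reset, 0.72 s per remaining
segment per forecast): the published stage timings are properties of
specific hardware, so the package reproduces the *budget arithmetic* —
trailing MU = dose rate × latency, and the largest duty cycle d with
(d · window · message rate) · t_segment + t_DIR + t_reset ≤ window —
rather than measuring hardware. Forecast intervals equal the forecast cost,
which shrinks with the remaining segment count, so the coverage update rate
rises toward the end of the fraction.

## Numerical choices and degenerate inputs

* Motion sync: nearest timestamp, earlier sample on ties (with 1 ns
  tolerance so floating-point noise cannot flip the tie-break), last sample
  held beyond the trace end — the causal choice.
* Beam flag semantics: a message's flag governs the interval it starts;
  a zero dose rate yields a stream that never turns on and downstream
  empty segment lists rather than errors.
* DVF sampling in algebra (inverse, composition) clamps coordinates to the
  grid hull (fields are boundary-tapered, so this only extends zeros);
  volume warps fill with a background value instead.
* Mask warping interpolates linearly and re-thresholds at 0.5, avoiding
  nearest-neighbour aliasing at 3 mm.
* Fixed-point DVF inversion is damped (step 0.5) with tolerance 10⁻³ mm;
  non-convergence is an error that reports the residual.
* Empty masks, empty diode selections, all-sub-threshold gamma references,
  MU cuts outside the plan, crossing MLC leaves, non-monotone streams:
  all are errors naming the offence (an all-zero diode vector warns and
  returns an empty selection).

## Problem sizes

The bundled studies use 64³ × 3 mm grids, a 240 MU / 9-segment plan for the
rigid sessions (~176 streamed segments at 420 MU/min and 5 Hz) and a
120 MU open-field plan for the deformable session (~86 segments, two 3 s
pauses); the statistical check accumulates 3-segment fractions 1000 times
on a small homogeneous grid. These sizes were chosen as the package's
standard desk-scale conditions: large enough that every mechanism
(band selection, coverage degradation, DIR recovery) operates on realistic
geometry, small enough to re-run routinely.

## Known limitations

Primary-beam-only dose (no scatter kernel, no electron-return effect at
tissue–air interfaces despite the 1.5 T context); mono-modal registration
with no DIR quality assurance; translations are consumed, not estimated
from images; film and diode physics are idealized; timing is a cost model,
not a measurement. Each of these sits behind a small interface
(`beam_model` / `register_demons` / `virtual_measurement` /
`session_config`) precisely so a faithful component can replace the
stand-in.
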
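# rtdose

Real-time dose reconstruction and dose-coverage forecasting for MR-guided
radiotherapy, at desk scale.

On an MR-linac, the machine streams its state — jaw and MLC leaf positions,
gantry angle, cumulative monitor units (MU) — at 5 Hz while the MR device
reports target motion (3D translations) or full 3D images of the anatomy.
`rtdose` simulates and evaluates the workflow that turns this stream into
clinically interpretable dose information *during* the fraction:

1. **Real-time reconstruction** — between two control points with the beam
   on, a beam segment is formed (ΔMU + aperture) and its dose is computed
   on the current anatomy (rigidly translated, or deformed via a
   registration-derived displacement field), then mapped back to the
   reference frame and accumulated.
2. **Planned dose to the same MU** — the dose the plan would have delivered
   by now on the unmoved anatomy; the difference against (1) isolates the
   dosimetric impact of intrafraction motion.
3. **Forecast** — (1) plus the remainder of the plan computed on the latest
   frozen anatomy, summarized as the CTV V95% (fraction of the target
   receiving ≥ 95 % of the prescription).

The dose model is an analytic primary beam on a 3 mm isotropic grid,

D(v) = ΔMU · O · F(u, v) · (SAD / r)² · exp(−μ d_rad),

with aperture fluence `F` (jaws ∩ MLC, Gaussian penumbra), inverse-square
falloff, exponential attenuation along the Siddon-traced radiological depth
`d_rad`, and an optional per-voxel multiplicative noise term with fixed
relative standard deviation (default 5 %) emulating a Monte Carlo engine's
statistical uncertainty. Everything around it is first-class and tested:
synthetic phantoms (a diode-array cylinder with 40 Hz time-resolved
readouts; a deformable water-bag/film setup), plan and control-point stream
generators, a demons-style deformable registrar with DVF algebra (warp,
inverse, composition), deviation metrics (σ/MAD over the 60–85 % dose band),
DVH coverage, 2 %/2 mm global gamma analysis, and duty-cycle/latency
accounting.

## Worked example

```r
library(rtdose)

ph    <- build_phantom("delta4_like")            # 64^3, 3 mm, 861 diodes
plan  <- make_plan(9, 8, 7.5, seed = 1, total_mu = 240)
model <- calibrate_output(plan, ph, beam_model())  # CTV mean = 102% of 7.5 Gy

rep <- run_session(plan, ph,
                   rigid_scenario("linear_drift", amplitude_mm = 10),
                   model, session_config(), seed = 11)
rep
#> <session_report:rigid> 176 segments, 240.0 MU delivered
#>   planned V95 100.0%, final forecast V95 98.2%
#>   final sigma_P 1.387 Gy, sigma_C 0.027 Gy (band of 139 diodes)
```

Under a 10 mm cranial-caudal drift the measured-vs-planned deviation σ_P
grows throughout delivery (1.387 Gy = 18.5 % of the 7.5 Gy fraction dose)
while the live-calculated dose stays with the measurement
(σ_C = 0.027 Gy, i.e. at the engine's statistical noise floor of
5 %/√176 per diode), and the forecast V95 falls from the planned 100 % to
98.2 % — the live system sees the coverage loss the plan cannot.

The same session on the deformable water-bag phantom (beam paused twice to
push a virtual roll under the setup) gives

```r
repd <- run_session(make_plan(1, 10, 7.5, seed = 2, total_mu = 120, field_v_cm = 10),
                    build_phantom("waterbag_film"), roll_scenario(),
                    beam_model(), session_config(), seed = 5)
#>   film gamma pass: planned 92.2%, accumulated 100.0%
```

— deformable accumulation explains the virtual film measurement better
than the static plan (2 %/2 mm global gamma, 5 % low-dose threshold).

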
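---
title: "Simulating couch-based respiratory motion compensation and its dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating couch-based respiratory motion compensation and its dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respcomp)
```

## The problem

Respiratory motion moves abdominal and thoracic targets by up to several
centimetres, predominantly along the superior–inferior (SI) axis. A
couch-mounted compensating platform can move opposite to the target so that,
in the beam's frame, the tumour stays nearly still; the target's motion is
read from an external surrogate (here a strain gauge pressed against the
abdomen, whose bridge voltage is linear in displacement). `respcomp`
implements the full evaluation loop for such a system in silico:

1. **Signal stage** — sinusoidal (amplitude 5/10/15 mm, period 4 s) and
   irregular breathing traces, plus the affine gauge transduction.
2. **Calibration** — a similar-triangle C-arm projection model and a
   least-squares gain/shift fit of surrogate to target.
3. **Compensation** — an inverted, latency-delayed couch (47 ms in the
   reference system) with optional gain error, actuator noise and a speed
   limit; the residual motion is `target + couch`.
4. **Dosimetry** — a separable error-function beam (3 × 3 cm field,
   300 cGy in 44.4 s = 11.1 cycles) accumulated on a virtual film that
   rides the residual motion, scored by 95%/5% isodose areas, in-field mean
   dose and the global 3%/3mm gamma index against the standstill film.

## Models and assumptions

### Breathing traces

The irregular generator concatenates raised-cosine cycles,
`x(τ) = A_k (1 − cos 2πτ)/2`, with per-cycle period
`T_k ~ N(T̄, σ_T)` and amplitude `A_k ~ N(1, cv) · pp/2`, plus a per-cycle
random-walk baseline, then rescales the whole trace so the global
peak-to-peak equals `displacement_pp` *exactly*. The exact rescale makes
the 10/20/30 mm arm labels literal rather than approximate. Raised cosine
is the simplest waveform with smooth end-exhale plateaus; no published
patient waveform or sampling rate was available to emulate, so only the
duration (60 s) and displacement scaling are reproduced, and all jitter
parameters are exposed (`period_sd = 0.3` s, `amplitude_cv = 0.15`,
`drift_sd = 0.5` mm are moderate-breather defaults). Real breathing also
shows AP/LR components, baseline shifts between sessions and occasional
apnoea; none of these are modelled, so passing tests say nothing about
multi-axis or non-stationary breathing.

The default sampling interval is 10 ms (100 Hz) so the 47 ms latency is a
fractional-sample shift handled by linear interpolation rather than a
whole-sample approximation.

### Geometry and calibration

Projection uses exact similar triangles: an in-plane displacement `b` at
source distance `a` images as `f = b·e/a` on the plane at distance `e`;
two objects sharing one image displacement satisfy `d/b = c/a`.
Displacements are treated as small in-plane translations (no divergence
correction across the displacement extent), which is exact for the
millimetre-scale strokes involved. No numeric values of `a`, `c`, `e` were
published; they are configuration inputs with no fidelity claim.

The gain/shift adjustment — performed manually under fluoroscopy on the
physical system — is implemented as ordinary least squares of target on
surrogate, since no algorithmic description exists. The shift is used only
to align the baseline position; it never enters the velocity path.

### Compensation and kinematic metrics

The couch is pure inverted-delayed tracking:
`couch(t) = −(1 + gain_error)·command(t − L) + ε`, `ε ~ N(0, σ_act)`.
No predictive filtering (Kalman, MPC) is modelled, deliberately. For a
sinusoid of amplitude A and period T this leaves a residual of amplitude
`2A sin(πL/T)` — 1.107 mm at A = 15 mm, T = 4 s, L = 47 ms — which the
tests verify to < 0.1%.

"Position error" and "compensating error" have no published definition;
both are implemented as mean absolute error (RMS and max available via
`stat =`), the compensating error being the MAE of the full chain's
residual. This matches the observation that the 47 ms delay makes the
compensating error exceed either system's own position error. The bench
error budgets (0.92/1.65/2.75 mm for the sine arms) are *inputs*:
`calibrate_actuator_noise()` bisects the actuator noise until the residual
MAE matches the budget, reusing the same seeded noise realisation so the
match is exact for that seed.

Per-breath displacements are measured by segmenting at end-exhale minima:
local minima separated by at least half the dominant period (taken from
the autocorrelation peak), accepted deepest-first. The rule is fully
deterministic; the generator's ground-truth cycle boundaries are used to
validate it. The compensation rate is `100·(1 − residual/target)` applied
to mean displacements; applied to the published per-patient means it
reproduces 9 of the 10 printed rates to one decimal (the remaining one
differs by 0.1, consistent with a different per-cycle averaging order).

### Beam model and dose accumulation

No film profile was published, so the beam is the standard broad-beam
separable model, `D = D₀·Px(x)·Py(y)` with
`P(u) = ½[erf((u+w/2)/σ√2) − erf((u−w/2)/σ√2)]` normalised to 1 at the
centre. The penumbra σ is not a free choice: it is calibrated by bisection
so the standstill 95% isodose area equals the measured 5.36 cm²
(tolerance 0.01 cm²), which yields σ ≈ 2.04 mm. The standstill 5% area of
this calibrated model is ~13.1 cm², not the measured 18.53 cm²; a single-σ
erf profile cannot match both ends of a film with low-dose tails
(scatter, film response), and we report rather than force it. The
delivery-rate ambiguity (a nominal machine rate vs the printed
300 cGy / 44.4 s pair) is resolved in favour of the printed pair:
`dose_rate = 300/44.4` cGy/s.

Dose on the moving film is the time integral of the static profile sampled
at `x − r(t)` (motion on the SI axis only, matching the single-axis
compensation scope), stepped at the trace `dt` (4440 steps for a full
delivery). For full-period sinusoidal motion this equals convolution with
the arcsine position density `1/(π√(A² − u²))`, and the test suite holds
the two routes to < 0.5% of the maximum dose; total dose is conserved to
< 0.1% whenever the grid margin exceeds `max|r| + 5σ`. The default raster
is 0.25 mm over 100 × 100 mm — an order finer than the 3 mm DTA, wide
enough for 30 mm strokes, and covering the 80 mm profile axis (film
centre at 40 mm, field 25–55 mm).

### Dose metrics

Isodose areas are pixel counts **referenced to the standstill maximum**
for every arm; referencing each film to its own maximum could never
produce the measured 0 cm² for the fully blurred arm. The gamma index is
the global-normalisation Low form: at each reference (standstill) point in
the nominal field, minimise
`√(|Δr|²/dta² + ΔD²/(3% · refmax)²)` over evaluated positions within
3·dta, bilinearly interpolated at dta/10 steps; a brute-force exhaustive
search at half that step is the test oracle (agreement within 0.05 in γ).
Restricting evaluation to the field is configurable (`eval_region = NULL`
scores the whole grid); no low-dose cutoff is applied by default because
none was documented. The 5%-area change under compensation uses the same
`(comp − uncomp)/standstill` convention as the 95% areas; its two extreme
magnitudes (3.2 and 33.8 points) match the published reduction range,
though for the 10 mm breathing arm the 5% area actually *grew* by 3.2
points — the sign is reported as computed.

## What the simulation does and does not reproduce

With the calibrated beam, the pipeline reproduces, deterministically:
the standstill 95% area (5.36 cm² by construction), the collapse of the
uncompensated 15 mm-sine 95% area to exactly 0 cm², the strict decrease of
the in-field passing rate with amplitude, 100% passing for the 10/20 mm
compensated arms, and every published worked-example number (compensation
rates from mean displacements; 95%-area improvements 15.3/76.9/86.4%).

Two published endpoints are *not* reproduced, for structural reasons we
consider informative rather than fixable:

* the fully blurred uncompensated arm scores ~13% in-field gamma, not 0%.
  Because motion blurs along one axis only, the evaluated film shares the
  reference's transverse penumbra, so reference points in a ~2 mm band at
  the transverse field edges always find an exact dose match within a
  fraction of the DTA. Any separable beam with single-axis blur behaves
  this way under a true minimum-search gamma.
* the 30 mm compensated arm scores ~88%, not 100%, when the residual is
  forced to a 2.75 mm MAE with Gaussian actuator noise: a Gaussian
  residual of that MAE has sd ≈ 3.35 mm, and the implied blur erodes the
  near-edge in-field dose by more than 3% over a band wider than the DTA.
  The published compensated areas imply an effective residual blur closer
  to 1.8 mm sd, i.e. the physical residual was not Gaussian with that
  marginal. The 10/20 mm budgets (0.92/1.65 mm) pass at 100%.

Film-specific effects — optical-density response, digitisation,
registration between films, analysis-software normalisation — are out of
scope, and are the most plausible source of the remaining differences.

## Problem sizes and numerical choices

The production configuration (0.25 mm pixels, 0.01 s steps, 44.4 s
delivery) runs the full seven-group experiment in well under a minute on
one core; property tests use a 0.5 mm raster and the experiment-level
tests a 0.02 s step, which leaves every tested property unchanged.
Penumbra calibration bisects σ on [0.05, 15] mm for 60 iterations or until
the pixel-counted area is within 0.01 cm². Gamma search uses a circular
offset mask of radius 3·dta; padded out-of-grid lookups contribute an
infinite γ (they carry no dose information) rather than being clamped.
Degenerate inputs fail loudly: zero-variance surrogates, constant traces
(no detectable cycles), non-uniform trace files, and grids smaller than
the field are all errors, not warnings.

## A worked example

```{r example, eval = FALSE}
library(respcomp)

cfg <- experiment_config(waveform = "sine",
                         comp_error_targets = c(0.92, 1.65, 2.75),
                         seed = 1)
exp <- run_experiment(cfg, outdir = "results/dose_experiment/sine")
exp$summary[, c("arm", "area95_cm2", "gamma_pass_pct", "improvement95_pct")]
```

The same drivers live under `analysis/`: `01_reference_metrics.R` (worked
examples on the bundled reference measurements), `02_kinematics.R`
(latency sweep and per-cycle statistics) and `03_dose_experiment.R` (the
full seven-group experiment for both waveforms).
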
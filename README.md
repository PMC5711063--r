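# respcomp

Simulation and dosimetric evaluation of couch-based respiratory motion
compensation, for medical-physics researchers studying intrafraction motion
management.

Respiratory motion displaces thoracic and abdominal targets by up to several
centimetres along the superior–inferior axis. A compensating couch moves
opposite to the target — driven by a strain-gauge surrogate of abdominal
motion — so the tumour stays nearly still in the beam frame. `respcomp`
re-creates the complete evaluation of such a system in silico:

* **Signals** — sinusoidal couch motion (amplitude A ∈ {5, 10, 15} mm,
  period T = 4 s) and irregular breathing traces with exact peak-to-peak
  scaling; affine gauge transduction `v = k·x + v₀ + ε`.
* **Calibration** — similar-triangle C-arm projection (`b·e/a = f`,
  `d/b = c/a`) and least-squares gain/shift fitting of surrogate to target.
* **Compensation** — inverted, latency-delayed tracking
  `couch(t) = −command(t − L)` with L = 47 ms, optional gain error, actuator
  noise and speed limit. For a sinusoid the residual has the closed form
  `2A·sin(πL/T)` (1.107 mm at A = 15 mm), which the tests verify.
* **Dosimetry** — a separable error-function beam (3 × 3 cm field, 300 cGy
  in 44.4 s = 11.1 cycles) with the penumbra σ calibrated so the standstill
  95% isodose area is 5.36 cm²; time-stepped dose accumulation on the moving
  virtual film (equal to arcsine-density convolution for full-period sine
  motion); 95%/5% isodose areas referenced to the standstill maximum; mean
  in-field dose; and the global 3%/3mm gamma index
  `γ(r) = min_{r'} √(|r−r'|²/dta² + ΔD²/(0.03·D_max)²)` with interpolated
  spatial search.
* **Kinematics** — position/compensating errors (MAE), per-breath cycle
  segmentation at end-exhale minima, per-cycle compensation rates
  `100·(1 − residual/target)`, Pearson correlation.

## Worked example

```r
library(respcomp)

cfg <- experiment_config(waveform = "sine",
                         comp_error_targets = c(0.92, 1.65, 2.75),
                         seed = 1)
exp <- run_experiment(cfg)
exp$summary[, c("arm", "area95_cm2", "gamma_pass_pct", "improvement95_pct")]
```

prints (0.25 mm raster, 0.01 s steps):

```
              arm area95_cm2 gamma_pass_pct improvement95_pct
       standstill       5.36          100.0                NA
 sine_10mm_uncomp       3.95           94.6                NA
   sine_10mm_comp       5.12          100.0              21.9
 sine_20mm_uncomp       1.85           48.0                NA
   sine_20mm_comp       4.66          100.0              52.4
 sine_30mm_uncomp       0.00           13.0                NA
   sine_30mm_comp       3.80           87.4              70.9
```

Reading: without compensation the 95% isodose area shrinks with motion
amplitude and vanishes for the 30 mm stroke, and the in-field gamma passing
rate falls monotonically; with 47 ms-latency compensation (actuator noise
calibrated to the 0.92/1.65/2.75 mm bench error budgets) most of the area
and passing rate are restored. `improvement95_pct` is
`100·(comp − uncomp)/standstill`.

The numbered drivers under `analysis/` narrate the full study:
`01_reference_metrics.R` applies the kinematic/dosimetric formulas to the
bundled reference measurements (per-patient compensation rates, area
improvements), `02_kinematics.R` explores the latency-residual closed form
and per-cycle statistics, and `03_dose_experiment.R` runs the seven-group
experiment for sine and breathing waveforms, writing tables under
`results/`.

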
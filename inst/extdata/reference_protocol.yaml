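# Reference irradiation protocol: seven groups (standstill + 3 uncompensated
# + 3 compensated arms), 4 s period, 44.4 s delivery of 300 cGy to a 3x3 cm
# field, 47 ms compensation latency, 3%/3mm in-field gamma.
waveform: sine
displacements_pp_mm: [10, 20, 30]
period_s: 4.0
duration_s: 44.4
dt_s: 0.01
norm_dose_cgy: 300
field_x_mm: 30
field_y_mm: 30
calibrate_area95_cm2: 5.36
grid_extent_mm: 100
grid_spacing_mm: 0.25
gauge_volts_per_mm: 0.5
gauge_offset_v: 0.1
gauge_noise_sd_v: 0.01
latency_s: 0.047
comp_error_targets_mm: [0.92, 1.65, 2.75]
gamma_dose_tol_pct: 3
gamma_dta_mm: 3
seed: 1
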
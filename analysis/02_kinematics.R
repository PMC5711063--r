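#!/usr/bin/env Rscript

# Kinematics of latency-limited reverse-motion compensation: closed-form
# check of the lagged-sinusoid residual, a latency sweep, and Table-3-style
# per-cycle compensation statistics for synthetic irregular breathers.
#
# Writes: results/kinematics/{latency_sweep.csv,per_cycle_breathers.csv}

suppressPackageStartupMessages(library(respcomp))
outdir <- "results/kinematics"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

# residual of an inverted, delayed sinusoid: amplitude 2 A sin(pi L / T)
cmd <- gen_sine(amplitude = 15, period = 4, duration = 44.4, dt = 0.01)
res47 <- residual_motion(cmd, simulate_couch(cmd,
                                             compensation_config(latency = 0.047)))
cat(sprintf("15 mm sine, 47 ms latency: max residual %.4f mm (closed form %.4f mm)\n",
            max(abs(res47$values)), 2 * 15 * sin(pi * 0.047 / 4)))

lat <- seq(0, 0.3, by = 0.01)
sweep <- do.call(rbind, lapply(lat, function(L) {
  r <- residual_motion(cmd, simulate_couch(cmd, compensation_config(latency = L)))
  data.frame(latency_s = L,
             max_residual_mm = max(abs(r$values)),
             mae_residual_mm = mean(abs(r$values)),
             closed_form_mm = 2 * 15 * sin(pi * L / 4))
}))
write.csv(sweep, file.path(outdir, "latency_sweep.csv"), row.names = FALSE)
cat(sprintf("latency sweep 0-300 ms written; at 47 ms the residual is %.2f%% of the 30 mm stroke\n\n",
            100 * max(abs(res47$values)) / 30))

# synthetic irregular breathers, compensated with latency only:
# per-cycle displacement statistics in the style of the human verification
rows <- list()
for (pp in c(10, 20, 30)) {
  tgt <- gen_breathing(breathing_params(displacement_pp = pp,
                                        amplitude_cv = 0.2, period_sd = 0.4,
                                        drift_sd = 0.3, seed = seed + pp))
  tgt <- resp_trace(tgt$values - mean(range(tgt$values)), dt = tgt$dt)
  couch <- simulate_couch(tgt, compensation_config(latency = 0.047))
  kin <- kinematics_report(tgt, couch)
  pc <- kin$per_cycle
  pc$displacement_pp_mm <- pp
  rows[[as.character(pp)]] <- pc
  cat(sprintf("breather %2d mm: target %5.2f mm/cycle, residual %4.2f mm/cycle, rate %.1f +- %.1f %%, r = %.3f\n",
              pp, kin$target_mean_disp, kin$residual_mean_disp,
              kin$comp_rate_mean, kin$comp_rate_sd, kin$pearson_r))
}
per_cycle <- do.call(rbind, rows)
write.csv(per_cycle, file.path(outdir, "per_cycle_breathers.csv"),
          row.names = FALSE)
cat("\nWith latency as the only error source, ~92% of each breath's excursion\n")
cat("is offset per cycle; measured systems add surrogate and actuator noise\n")
cat("on top of this floor (bench compensating-error budget 0.92-2.75 mm).\n")
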
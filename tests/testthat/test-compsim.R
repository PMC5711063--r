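test_that("ideal couch is the exact inverse; latency gives the closed-form residual", {
  cmd <- gen_sine(15, 4, 44.4, 0.01)

  ideal <- simulate_couch(cmd, compensation_config(latency = 0))
  expect_equal(ideal$values, -cmd$values, tolerance = 1e-12)
  r0 <- residual_motion(cmd, ideal)
  expect_true(all(abs(r0$values) < 1e-12))

  # lagged inverted sinusoid: residual amplitude 2 A sin(pi L / T)
  lag <- simulate_couch(cmd, compensation_config(latency = 0.047))
  r <- residual_motion(cmd, lag)
  expect_equal(max(abs(r$values)), 2 * 15 * sin(pi * 0.047 / 4),
               tolerance = 1e-3)

  # constant command: couch constant at -command once the lag has elapsed
  const <- resp_trace(rep(4.2, 500), dt = 0.01)
  cc <- simulate_couch(const, compensation_config(latency = 0.047))
  expect_true(all(cc$values == -4.2))

  # uncompensated arm: zero couch leaves the target as residual
  zero <- resp_trace(rep(0, length(cmd$values)), dt = 0.01)
  expect_equal(residual_motion(cmd, zero)$values, cmd$values)

  # zero latency/noise/gain error compensates any waveform completely
  br <- gen_breathing(breathing_params(displacement_pp = 20, seed = 5,
                                       duration = 30))
  rb <- residual_motion(br, simulate_couch(br, compensation_config(latency = 0)))
  expect_true(all(abs(rb$values) < 1e-12))
})

test_that("speed-limited couch never exceeds the actuator limit", {
  cmd <- gen_sine(15, 4, 20, 0.01)  # peak speed 2*pi*15/4 = 23.6 mm/s
  cfg <- compensation_config(latency = 0, max_speed = 10)
  couch <- simulate_couch(cmd, cfg)
  expect_lte(max(abs(diff(couch$values))), 10 * 0.01 + 1e-12)
  # limit well above the commanded speed changes nothing
  free <- simulate_couch(cmd, compensation_config(latency = 0, max_speed = 100))
  expect_equal(free$values, -cmd$values, tolerance = 1e-12)
})

test_that("position error statistics match folded-normal and invariance properties", {
  x <- gen_sine(10, 4, 40, 0.01)
  expect_equal(position_error(x, x), 0)
  shifted <- resp_trace(x$values + 1, dt = x$dt)
  expect_equal(position_error(x, shifted), 1)
  expect_equal(position_error(x, shifted, stat = "rms"), 1)
  expect_equal(position_error(x, shifted, stat = "max"), 1)

  # mean |N(0, 1.25)| = 1.25 * sqrt(2/pi)
  set.seed(8)
  n <- 1e4
  noisy <- resp_trace(x$values[1] + rnorm(n, 0, 1.25), dt = 0.01)
  base <- resp_trace(rep(x$values[1], n), dt = 0.01)
  expect_equal(position_error(base, noisy), 1.25 * sqrt(2 / pi),
               tolerance = 0.03)

  # translation invariance
  a <- resp_trace(x$values + 5, dt = x$dt)
  b <- resp_trace(noisy$values[seq_along(x$values)] + 5, dt = x$dt)
  b0 <- resp_trace(noisy$values[seq_along(x$values)], dt = x$dt)
  expect_equal(position_error(a, b), position_error(x, b0))
})

test_that("compensation rate reproduces the self-consistent reference patients", {
  expect_equal(round(compensation_rate(7.67, 1.92), 1), 75.0)
  expect_equal(round(compensation_rate(21.39, 7.00), 1), 67.3)
  expect_equal(round(compensation_rate(9.50, 2.44), 1), 74.3)

  hv <- reference_measurements("human_verification")
  consistent <- c(1, 2, 3, 4, 5, 7)
  got <- round(compensation_rate(hv$sim_mean_mm[consistent],
                                 hv$tgt_mean_mm[consistent]), 1)
  expect_equal(got, hv$rate_pct[consistent])

  expect_equal(compensation_rate(12.3, 0), 100)
  expect_error(compensation_rate(0, 1), "target_mean")
})

test_that("cycle segmentation agrees with the generator's ground truth", {
  s <- gen_sine(5, 4, 20, 0.01)
  pp <- cycle_displacements(s)
  expect_true(all(abs(pp - 10) < 1e-9))
  expect_equal(length(pp), 4)

  tr <- gen_breathing(breathing_params(displacement_pp = 20,
                                       amplitude_cv = 0.2, seed = 3))
  det <- cycle_displacements(tr)
  orc <- cycle_displacements(tr, boundaries = attr(tr, "cycle_bounds"))
  expect_equal(mean(det), mean(orc), tolerance = 0.02)
  # detected end-exhale minima sit on (interior) true boundaries
  b_det <- attr(det, "boundaries")
  b_true <- attr(orc, "boundaries")
  expect_true(mean(vapply(b_det, function(i) min(abs(i - b_true)),
                          numeric(1)) <= 25) > 0.8)  # within 0.25 s

  expect_error(cycle_displacements(resp_trace(rep(1, 1000), 0.01)),
               "degenerate")
})

test_that("pearson correlation handles exact, anti- and constructed correlations", {
  x <- gen_sine(5, 4, 30, 0.01)
  y <- resp_trace(2 * x$values + 1, dt = x$dt)
  expect_equal(pearson(x, y), 1)
  expect_equal(pearson(x, resp_trace(-x$values, dt = x$dt)), -1)

  set.seed(13)
  n <- 6000
  a <- rnorm(n)
  b <- 0.95 * a + sqrt(1 - 0.95^2) * rnorm(n)
  expect_equal(pearson(resp_trace(a, 0.01), resp_trace(b, 0.01)), 0.95,
               tolerance = 0.01)

  expect_error(pearson(resp_trace(rep(1, 10), 0.01), resp_trace(1:10, 0.01)),
               "zero variance")
})

test_that("kinematics report assembles per-cycle rates and chain errors", {
  tgt <- gen_sine(10, 4, 44.4, 0.01)
  cfg <- compensation_config(latency = 0.047, actuator_noise_sd = 0.5,
                             seed = 3)
  couch <- simulate_couch(tgt, cfg)
  rep <- kinematics_report(tgt, couch)
  expect_equal(rep$compensating_error,
               mean(abs(residual_motion(tgt, couch)$values)))
  expect_true(rep$comp_rate_mean > 80 && rep$comp_rate_mean <= 100)
  expect_true(abs(rep$pearson_r) <= 1)
  expect_equal(nrow(rep$per_cycle), length(cycle_displacements(tgt)))
  expect_equal(rep$per_cycle$rate_pct,
               compensation_rate(rep$per_cycle$target_pp_mm,
                                 rep$per_cycle$residual_pp_mm))
  # zero couch: rate 0, pearson undefined
  zero <- resp_trace(rep(0, length(tgt$values)), dt = 0.01)
  rep0 <- kinematics_report(tgt, zero)
  expect_equal(rep0$comp_rate_mean, 0, tolerance = 1e-9)
  expect_true(is.na(rep0$pearson_r))
})

test_that("actuator-noise calibration hits a compensating-error budget exactly", {
  cmd <- gen_sine(15, 4, 44.4, 0.01)
  cfg <- compensation_config(latency = 0.047, seed = 7)
  for (target in c(0.92, 1.65, 2.75)) {
    cal <- calibrate_actuator_noise(cmd, cfg, target)
    got <- mean(abs(residual_motion(cmd, simulate_couch(cmd, cal))$values))
    expect_equal(got, target, tolerance = 1e-3)
  }
  # budget below the latency floor: returns the noiseless configuration
  tiny <- calibrate_actuator_noise(cmd, cfg, 1e-4)
  expect_equal(tiny$actuator_noise_sd, 0)
})
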
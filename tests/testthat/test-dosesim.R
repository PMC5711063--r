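# coarser raster than the production default keeps these checks quick while
# leaving margin around the 30 mm field
spec_t <- dose_grid_spec(extent = 100, spacing = 0.5)

test_that("static beam profile is normalised, separable and edge-consistent", {
  beam <- beam_model(penumbra_sigma = 3)
  g <- static_dose(beam, spec_t)
  ic <- which(g$x == 0)
  expect_equal(g$dose[ic, ic], 300)           # centre pixel = norm dose
  expect_equal(max(g$dose), 300)

  # hard-edge limit: uniform inside the field, zero outside
  bh <- beam_model(penumbra_sigma = 0.05)
  gh <- static_dose(bh, spec_t)
  inside <- abs(gh$x) < 14
  outside <- abs(gh$x) > 16
  expect_true(all(abs(gh$dose[inside, inside] - 300) < 1e-6))
  expect_true(all(gh$dose[outside, outside] < 1e-6))

  # at the field edge the 1D profile is half the central value (small sigma)
  px <- gh$dose[ic, ] / 300
  iedge <- which(gh$x == 15)
  expect_equal(px[iedge], 0.5, tolerance = 1e-3)

  expect_error(static_dose(beam, dose_grid_spec(extent = 20, spacing = 0.5)),
               "smaller than the field")
})

test_that("penumbra calibration hits the standstill 95% area and is monotone", {
  spec <- dose_grid_spec(extent = 100, spacing = 0.25)
  beam <- calibrate_penumbra(5.36, beam_model(), spec)
  g <- static_dose(beam, spec)
  expect_equal(isodose_area(g, 95, max(g$dose)), 5.36, tolerance = 0.01)

  # larger sigma always shrinks the 95% area
  areas <- vapply(c(0.5, 1, 2, 3, 4, 6), function(s) {
    gs <- static_dose(beam_model(penumbra_sigma = s), spec_t)
    isodose_area(gs, 95, max(gs$dose))
  }, numeric(1))
  expect_true(all(diff(areas) < 0))

  expect_error(calibrate_penumbra(20, beam_model(), spec_t), "between 0")
})

test_that("accumulation reproduces statics, shifts and the arcsine convolution", {
  beam <- beam_model(penumbra_sigma = 2)
  dur <- 44.4

  still <- resp_trace(rep(0, 4441), dt = 0.01)
  g0 <- accumulate_dose(beam, still, dur, spec_t)
  gs <- static_dose(beam, spec_t)
  expect_equal(g0$dose, gs$dose, tolerance = 1e-12)

  # constant 5 mm offset shifts the distribution by -5 mm along x
  off <- resp_trace(rep(5, 4441), dt = 0.01)
  g5 <- accumulate_dose(beam, off, dur, spec_t)
  shift_px <- round(5 / spec_t$spacing)
  nx <- length(spec_t$x)
  expect_equal(g5$dose[, (shift_px + 1):nx],
               gs$dose[, 1:(nx - shift_px)], tolerance = 1e-9)

  # full-period sine motion equals the arcsine-density convolution
  for (A in c(5, 10)) {
    mot <- gen_sine(A, 4, 4, 0.01)
    ga <- accumulate_dose(beam, mot, 4, spec_t)
    ic <- which(ga$y == 0)
    got <- ga$dose[ic, ]
    want <- arcsine_blur_profile(ga$x, A, beam$field_x,
                                 beam$penumbra_sigma) *
      beam$dose_rate * 4
    expect_lt(max(abs(got - want)) / max(got), 0.005)
  }

  # linear in duration and dose rate
  g1 <- accumulate_dose(beam, still, 11.1, spec_t)
  expect_equal(4 * g1$dose, g0$dose, tolerance = 1e-9)
  beam2 <- beam_model(penumbra_sigma = 2, dose_rate = 2 * beam$dose_rate)
  g2 <- accumulate_dose(beam2, still, 11.1, spec_t)
  expect_equal(g2$dose, 2 * g1$dose, tolerance = 1e-9)

  short <- gen_sine(5, 4, 10, 0.01)
  expect_error(accumulate_dose(beam, short, 44.4, spec_t), "cover")
})

test_that("motion redistributes dose without creating or destroying it", {
  beam <- beam_model(penumbra_sigma = 2)
  gs <- static_dose(beam, spec_t)
  total0 <- sum(gs$dose)
  for (A in c(5, 15)) {
    mot <- gen_sine(A, 4, 44.4, 0.01)
    g <- accumulate_dose(beam, mot, 44.4, spec_t)
    expect_lt(abs(sum(g$dose) - total0) / total0, 1e-3)
  }
  br <- centre <- gen_breathing(breathing_params(displacement_pp = 20,
                                                 seed = 2, duration = 60))
  br$values <- br$values - mean(range(br$values))
  g <- accumulate_dose(beam, br, 44.4, spec_t)
  expect_lt(abs(sum(g$dose) - total0) / total0, 1e-3)
})

test_that("profiles follow the 0-80 mm axis convention and motion symmetry", {
  beam <- beam_model(penumbra_sigma = 2)
  gs <- static_dose(beam, spec_t)
  pr <- dose_profile(gs)
  expect_equal(pr$position_mm[which.max(pr$dose)], 40, tolerance = 0.5)
  # nominal field 25-55 mm: flat (>95%) well inside, low outside
  flat <- pr$position_mm > 25 + 4 * 2 & pr$position_mm < 55 - 4 * 2
  expect_true(all(pr$dose[flat] > 0.95 * max(pr$dose)))
  expect_true(all(pr$dose[pr$position_mm < 15] < 0.05 * max(pr$dose)))

  # symmetric motion (whole periods) keeps the profile symmetric about 40 mm
  mot <- gen_sine(10, 4, 44.4, 0.01)
  g <- accumulate_dose(beam, mot, 44, spec_t)
  prm <- dose_profile(g)
  expect_lt(max(abs(prm$dose - rev(prm$dose))) / max(prm$dose), 1e-3)

  # constant offset shifts the profile by the offset
  off <- resp_trace(rep(5, 4441), dt = 0.01)
  g5 <- accumulate_dose(beam, off, 44.4, spec_t)
  pro <- dose_profile(g5)
  expect_equal(pro$position_mm[which.max(pro$dose)], 35, tolerance = 1)
})

test_that("dose grids round-trip through delimited text with sidecar", {
  beam <- beam_model(penumbra_sigma = 2)
  g <- static_dose(beam, dose_grid_spec(extent = 40, spacing = 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dose_grid(g, path)
  back <- read_dose_grid(path)
  expect_equal(back$dose, g$dose, tolerance = 1e-9)
  expect_equal(back$x, g$x)
  expect_equal(back$spacing, g$spacing)

  # shape mismatch against the sidecar is rejected
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  side$nx <- side$nx + 1
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_dose_grid(path), "sidecar")
})
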
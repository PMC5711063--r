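test_that("isodose areas count pixels against the reference maximum", {
  # uniform 2 x 2 cm block at 100%
  spec <- dose_grid_spec(extent = 40, spacing = 0.5)
  d <- matrix(0, length(spec$y), length(spec$x))
  d[abs(spec$y) < 10, abs(spec$x) < 10] <- 100
  g <- dose_grid(d, spec)
  expect_equal(isodose_area(g, 95, 100), 3.8025)  # (39 * 0.5 mm)^2 block
  expect_equal(isodose_area(g, 95, 100), isodose_area(g, 5, 100))

  # monotone in level, 5% area >= 95% area on any grid
  gb <- static_dose(beam_model(penumbra_sigma = 2), spec)
  lv <- c(5, 25, 50, 75, 95)
  areas <- vapply(lv, isodose_area, numeric(1), grid = gb,
                  reference_max = max(gb$dose))
  expect_true(all(diff(areas) < 0))
  expect_error(isodose_area(gb, 0, 100), "level")
})

test_that("improvement formula reproduces the published area triples", {
  expect_equal(round(improvement(4.6, 3.78, 5.36), 1), 15.3)
  expect_equal(round(improvement(4.12, 0, 5.36), 1), 76.9)
  expect_equal(round(improvement(4.8, 0.17, 5.36), 1), 86.4)
  expect_equal(improvement(2.2, 2.2, 5.36), 0)
  expect_error(improvement(1, 1, 0), "standstill")
})

test_that("mean field dose is standstill-relative and decreases under blur", {
  spec <- dose_grid_spec(extent = 100, spacing = 0.5)
  beam <- beam_model(penumbra_sigma = 2)
  gs <- static_dose(beam, spec)
  expect_equal(mean_field_dose(gs, gs), 100)
  half <- dose_grid(gs$dose / 2, spec)
  expect_equal(mean_field_dose(half, gs), 50)

  last <- 100
  for (A in c(2.5, 5, 7.5)) {
    g <- accumulate_dose(beam, gen_sine(A, 4, 44.4, 0.01), 44.4, spec)
    mfd <- mean_field_dose(g, gs)
    expect_lt(mfd, last)  # any motion lowers the in-field mean
    last <- mfd
  }
})

test_that("gamma identity, boundary scaling and tolerance monotonicity hold", {
  g <- random_dose_grid(n = 25, spacing = 1, seed = 2)
  p <- gamma_params(eval_region = c(-8, 8, -8, 8), interp_step = 0.3)
  res <- gamma_index(g, g, p)
  expect_equal(res$pass_pct, 100)
  expect_true(all(res$gamma < 1e-9))

  # scaling by exactly 1 + tol/100 of the global max passes at flat regions
  flat <- dose_grid(matrix(80, 41, 41), dose_grid_spec(40, 1))
  up <- dose_grid(flat$dose * 1.03, dose_grid_spec(40, 1))
  resf <- gamma_index(up, flat, gamma_params(eval_region = c(-10, 10, -10, 10),
                                             interp_step = 0.3))
  expect_true(all(resf$gamma <= 1 + 1e-6))
  expect_equal(resf$pass_pct, 100)

  # shrinking either tolerance never increases the passing rate
  ev <- random_dose_grid(n = 25, spacing = 1, seed = 9)
  passes <- function(tol, dta) {
    gamma_index(ev, g, gamma_params(dose_tol = tol, dta = dta,
                                    eval_region = c(-8, 8, -8, 8),
                                    interp_step = dta / 10))$pass_pct
  }
  expect_gte(passes(3, 3), passes(1.5, 3))
  expect_gte(passes(3, 3), passes(3, 1.5))

  # symmetric under simultaneous translation of both grids
  sh <- function(gr) {
    d <- gr$dose
    d2 <- cbind(d[, 3:ncol(d)], d[, 1:2])
    dose_grid(d2, dose_grid_spec(24, 1))
  }
  p8 <- gamma_params(eval_region = c(-5, 5, -5, 5), interp_step = 0.3,
                     search_radius = 4)
  a <- gamma_index(ev, g, p8)$pass_pct
  ev2 <- random_dose_grid(n = 25, spacing = 1, seed = 9)
  b <- gamma_index(sh(ev2), sh(g), p8)$pass_pct
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("interpolated gamma search agrees with the brute-force oracle", {
  for (seed in c(3, 17)) {
    ref <- random_dose_grid(n = 21, spacing = 1, seed = seed)
    ev <- random_dose_grid(n = 21, spacing = 1, seed = seed + 100)
    # make the evaluated grid a perturbed version of the reference
    ev <- dose_grid(0.7 * ref$dose + 0.3 * ev$dose, dose_grid_spec(20, 1))
    p <- gamma_params(eval_region = c(-5, 5, -5, 5), interp_step = 0.3,
                      search_radius = 6)
    got <- gamma_index(ev, ref, p)
    want <- brute_gamma(ev, ref, dose_tol = 3, dta = 3,
                        eval_region = c(-5, 5, -5, 5), search_radius = 6,
                        step = 0.15)
    expect_lt(max(abs(got$gamma - want$gamma)), 0.05)
  }
})

test_that("dose report bundles the per-arm metrics consistently", {
  spec <- dose_grid_spec(extent = 80, spacing = 0.5)
  beam <- beam_model(penumbra_sigma = 2)
  gs <- static_dose(beam, spec)
  g <- accumulate_dose(beam, gen_sine(5, 4, 44.4, 0.01), 44.4, spec)
  rep <- dose_report(g, gs)
  expect_equal(rep$area95, isodose_area(g, 95, max(gs$dose)))
  expect_gte(rep$area5, rep$area95)
  expect_true(rep$gamma_pass >= 0 && rep$gamma_pass <= 100)
  expect_lt(rep$mean_field_dose_pct, 100)
})
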
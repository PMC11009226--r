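test_that("noise-free two-Voigt refit recovers all six shape parameters", {
  sp <- simulate_ftir(ftir_params_2260(), 23)[[1]]
  fit <- fit_two_voigt(sp)
  truth <- list(shb = sp$metadata$true_shb, whb = sp$metadata$true_whb)
  for (side in c("shb", "whb")) for (fld in c("center", "sigma", "gamma")) {
    expect_lt(abs(fit[[side]][[fld]] - truth[[side]][[fld]]) /
                abs(truth[[side]][[fld]]), 0.005)
  }
  # printed-band benchmarks: 13.1 cm-1 split, 2.260 area ratio
  expect_lt(abs((fit$whb$center - fit$shb$center) - 13.1), 0.2)
  expect_lt(abs(fit$shb$area / fit$whb$area - 2.260) / 2.260, 0.01)
  expect_lt(fit$residual_rms, 1e-8 * max(sp$absorbance))
})

test_that("component labels are sorted by center regardless of initialization", {
  sp <- simulate_ftir(ftir_gen_params(), 50)[[1]]
  init_swapped <- list(
    shb = voigt_component(1622, 4, 1.5, 0.3),   # deliberately the WHB guess
    whb = voigt_component(1609, 4, 1.5, 0.7)
  )
  fit <- fit_two_voigt(sp, init = init_swapped)
  expect_lt(fit$shb$center, fit$whb$center)
})

test_that("fitted areas add up to the integrated band area", {
  # wide grid so the slow Lorentzian tails are inside the integration range
  sp <- simulate_ftir(ftir_gen_params(grid = seq(1300, 1930, by = 1)),
                      c(23, 63))
  for (s in sp) {
    fit <- fit_two_voigt(s)
    band <- chex2dir:::trapz(s$wavenumber,
                             s$absorbance - fit$baseline[1])
    expect_lt(abs((fit$shb$area + fit$whb$area) - band) / band, 0.01)
  }
})

test_that("a pure one-component band pins the second area at its lower bound", {
  x <- seq(1540, 1690, by = 1)
  y <- voigt_profile(x, voigt_component(1607.8, 3.8, 1.3, 1))
  sp <- spectrum1d(x, y, temperature = 23)
  init <- list(shb = voigt_component(1607.8, 3.8, 1.3, 1),
               whb = voigt_component(1620.9, 3.8, 1.3, 0.05))
  fit <- fit_two_voigt(sp, init = init)
  expect_lt(fit$whb$area, 1e-6)
  expect_lt(fit$residual_rms, 1e-10 * max(y))
})

test_that("automatic initialization refuses spectra without two minima", {
  x <- seq(1540, 1690, by = 1)
  y <- voigt_profile(x, voigt_component(1610, 3.8, 1.3, 1))
  sp <- spectrum1d(x, y)
  expect_error(fit_two_voigt(sp), "init")
})

test_that("peak drift rate is recovered from a temperature series", {
  temps <- c(23, 33, 43, 53, 63, 73, 85)
  sp <- simulate_ftir(ftir_gen_params(), temps)
  fits <- lapply(sp, fit_two_voigt)
  shift <- peak_shift_rate(fits, "shb")
  expect_lt(abs(shift$slope - 0.07), 1e-3)
  # drift-free component list
  flat <- lapply(temps, function(tc)
    list(temperature = tc, shb = list(center = 1607.8),
         whb = list(center = 1620.9)))
  s0 <- peak_shift_rate(flat, "shb")
  expect_equal(s0$slope, 0, tolerance = 1e-12)
  expect_equal(s0$se, 0, tolerance = 1e-12)
  expect_error(peak_shift_rate(fits[1:2]), "3 temperatures")
})

test_that("noisy center drift is recovered within its sampling error", {
  # OLS sampling-distribution check on synthetic center series
  set.seed(42)
  temps <- c(23, 33, 43, 53, 63, 73, 85)
  for (rep in 1:5) {
    centers <- 1607.8 + 0.10 * (temps - 23) + rnorm(7, sd = 0.1)
    fits <- lapply(seq_along(temps), function(i)
      list(temperature = temps[i], shb = list(center = centers[i])))
    s <- peak_shift_rate(fits, "shb")
    expect_lt(abs(s$slope - 0.10), 3 * s$se)
  }
})

test_that("spectrum validation enforces the grid contract", {
  expect_error(spectrum1d(20:1 * 1.0, 1:20), "increasing")
  expect_error(spectrum1d(1:10, 1:10), "16 points")
  p <- ftir_gen_params(grid = seq(1595, 1630, by = 1))
  expect_error(simulate_ftir(p, 23), "does not cover")
})
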
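test_that("the dipole-corrected equilibrium constant follows its definition", {
  # direct arithmetic oracle from the printed 23 degC inputs
  k <- equilibrium_constant(1, 2.260, mu_shb = 0.344, mu_whb = 0.321)
  expect_equal(k, (1 / 2.260) * (0.344 / 0.321)^2, tolerance = 1e-12)
  expect_equal(equilibrium_constant(2, 2, 0.3, 0.3), 1)
  expect_equal(equilibrium_constant(4, 6, 0.3, 0.35),
               equilibrium_constant(8, 12, 0.3, 0.35))
  expect_error(equilibrium_constant(-1, 2, 0.3, 0.3), "positive")
})

test_that("van't Hoff regression inverts noise-free thermodynamics exactly", {
  tk <- celsius_to_kelvin(c(23, 33, 43, 53, 63, 73, 85))
  keq <- keq_from_thermo(6.22, 15.34, tk)
  vh <- vant_hoff_fit(tk, keq)
  expect_equal(vh$dH, 6.22, tolerance = 1e-10)
  expect_equal(vh$dS, 15.34, tolerance = 1e-10)
  expect_error(vant_hoff_fit(tk[1:2], keq[1:2]), "3 temperatures")
})

test_that("rescaling K_eq shifts only the entropy, by exactly R ln f", {
  tk <- celsius_to_kelvin(seq(20, 90, by = 10))
  keq <- keq_from_thermo(6.22, 15.34, tk)
  for (f in c(0.25, 3.7)) {
    vh <- vant_hoff_fit(tk, keq * f)
    expect_lt(abs(vh$dH - 6.22), 1e-9)
    expect_equal(vh$dS, 15.34 + R_GAS * log(f), tolerance = 1e-10)
  }
})

test_that("noisy van't Hoff input recovers the enthalpy within its error", {
  set.seed(314)
  tk <- celsius_to_kelvin(c(23, 33, 43, 53, 63, 73, 85))
  keq0 <- keq_from_thermo(6.22, 15.34, tk)
  for (rep in 1:5) {
    vh <- vant_hoff_fit(tk, exp(log(keq0) + rnorm(7, sd = 0.05)))
    expect_lt(abs(vh$dH - 6.22), 3 * vh$dH_se)
  }
})

test_that("Gibbs energy follows dG = dH - T dS and the log-K identity", {
  expect_equal(gibbs(6.22, 0, 296.15), 6.22)
  tk <- celsius_to_kelvin(c(23, 50, 60, 85))
  keq <- keq_from_thermo(6.22, 15.34, tk)
  expect_equal(gibbs(6.22, 15.34, tk), -R_GAS * tk * log(keq) / 1000,
               tolerance = 1e-9)
  withse <- gibbs(6.22, 15.34, 296.15, dH_se = 0.25, dS_se = 0.76)
  expect_true(withse$dG_se > 0)
  expect_error(gibbs(1, 1, -3), "positive")
})

test_that("thermo_from_areas assembles a consistent thermodynamic record", {
  tk <- celsius_to_kelvin(c(23, 33, 43, 53, 63, 73, 85))
  keq <- keq_from_thermo(6.22, 15.34, tk)
  a_shb <- rep(1, length(keq))
  a_whb <- keq * (0.321 / 0.344)^2     # areas that encode exactly this keq
  th <- thermo_from_areas(a_shb, a_whb, tk - 273.15)
  expect_equal(th$keq, keq, tolerance = 1e-12)
  expect_equal(th$dH, 6.22, tolerance = 1e-9)
  expect_equal(th$dipole_ratio_sq, (0.344 / 0.321)^2)
  expect_equal(th$dG$dG, th$dH - tk * th$dS / 1000, tolerance = 1e-9)
})

test_that("dipole sensitivity rescales the entropy and preserves the enthalpy", {
  tk <- celsius_to_kelvin(c(23, 33, 43, 53, 63, 73, 85))
  keq <- keq_from_thermo(6.22, 15.34, tk)
  th <- thermo_from_areas(rep(1, 7), keq * (0.321 / 0.344)^2, tk - 273.15)
  sens <- dipole_sensitivity(th, c(0.321, 0.5))
  # identity alternative reproduces the base fit
  expect_equal(sens$dH[1], th$dH, tolerance = 1e-12)
  expect_equal(sens$dS[1], th$dS, tolerance = 1e-12)
  # any alternative: dH invariant, dS shifted by R ln(factor)
  expect_equal(sens$dH[2], th$dH, tolerance = 1e-9)
  expect_equal(sens$dS[2] - th$dS, R_GAS * log(sens$factor[2]),
               tolerance = 1e-10)
  expect_error(dipole_sensitivity(th, c(0.3, -1)), "positive")
})
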
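test_that("normalization is scale invariant and unit-normalizes its window", {
  s <- simulate_2dir_series(exchange_gen_params(waiting_times = c(0, 0.3, 1)))
  gp <- s$metadata$params
  nw <- spectral_window(gp$freq_shb_01 - 2.5, gp$freq_shb_01 + 2.5,
                        gp$freq_shb_01 - 13 - 2.5, gp$freq_shb_01 - 13 + 2.5)
  n1 <- normalize_series(s, nw)
  s2 <- s
  s2$matrices <- lapply(s$matrices, function(m) 37.2 * m)
  n2 <- normalize_series(s2, nw)
  expect_equal(n1$matrices, n2$matrices, tolerance = 1e-12)
  for (i in seq_along(n1$matrices))
    expect_equal(abs(chex2dir:::window_integral(n1, n1$matrices[[i]], nw)), 1,
                 tolerance = 1e-12)
})

test_that("normalization cancels a common lifetime decay when exchange is off", {
  # all peaks decay as exp(-T_w/0.67); the normalized low-frequency 1->2
  # diagonal magnitude must then be constant in T_w
  p <- exchange_gen_params(tau_forward = 1e6, tau_reverse = 1e6,
                           t1_shb = 0.67, t1_whb = 0.67,
                           waiting_times = seq(0, 2, 0.25))
  s <- simulate_2dir_series(p)
  nw <- spectral_window(1607.8 - 2.5, 1607.8 + 2.5,
                        1607.8 - 13 - 2.5, 1607.8 - 13 + 2.5)
  raw <- vapply(s$matrices,
                function(m) chex2dir:::window_integral(s, m, nw), numeric(1))
  expect_gt(abs(raw[1] / raw[length(raw)]), 10)   # raw series really decays
  n <- normalize_series(s, nw)
  dw <- spectral_window(1607.8 - 2.5, 1607.8 + 2.5,
                        1607.8 - 13 - 2.4, 1607.8 - 13 + 2.6)
  mag <- vapply(n$matrices,
                function(m) chex2dir:::window_integral(n, m, dw), numeric(1))
  expect_lt(max(abs(mag / mag[1] - 1)), 0.01)
})

test_that("reference subtraction zeroes T_w = 0 and static series", {
  s <- simulate_2dir_series(exchange_gen_params(waiting_times = c(0, 0.5, 2)))
  d <- subtract_reference(s)
  expect_equal(max(abs(d$matrices[[1]])), 0)
  # static input: no exchange, no decay
  p0 <- exchange_gen_params(tau_forward = 1e12, tau_reverse = 1e12,
                            t1_shb = 1e12, t1_whb = 1e12,
                            waiting_times = c(0, 1, 2))
  d0 <- subtract_reference(simulate_2dir_series(p0))
  expect_lt(max(vapply(d0$matrices, function(m) max(abs(m)), numeric(1))),
            1e-9)
  s$waiting_times <- s$waiting_times + 0.05
  expect_error(subtract_reference(s), "T_w = 0")
})

test_that("cross-peak differences grow monotonically without noise", {
  s <- simulate_2dir_series(exchange_gen_params())
  pr <- exchange_protocol(s)
  expect_true(all(diff(pr$trace$magnitude) > -1e-12))
})

test_that("the cross trace follows the generator closed form", {
  s <- simulate_2dir_series(exchange_gen_params(tau_forward = 0.53))
  pr <- exchange_protocol(s)
  tw <- pr$trace$waiting_time
  model <- 1 - exp(-tw / 0.53)
  fit <- lm(pr$trace$magnitude ~ model)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("an all-zero difference series yields an all-zero trace", {
  s <- simulate_2dir_series(exchange_gen_params(waiting_times = c(0, 1, 2)))
  z <- s
  z$matrices <- lapply(s$matrices, function(m) m * 0)
  cw <- spectral_window(1605.3, 1610.3, 1618.4, 1623.4)
  expect_equal(cross_peak_trace(z, cw)$magnitude, c(0, 0, 0))
  far <- spectral_window(1400, 1410, 1600, 1610)
  expect_error(cross_peak_trace(z, far), "outside")
})

test_that("the fitted time constant is insensitive to the window size", {
  s <- simulate_2dir_series(isolated_2dir_params(tau_forward = 0.5))
  pr5 <- exchange_protocol(s, window_size = 5)
  pr10 <- exchange_protocol(s, cross_window = spectral_window(
    1580 - 5, 1580 + 5, 1640 - 5, 1640 + 5),
    norm_window = pr5$norm_window)
  expect_gt(max(pr10$trace$magnitude), max(pr5$trace$magnitude))
  expect_lt(abs(pr10$kinetics$tau_forward / pr5$kinetics$tau_forward - 1),
            0.01)
})

test_that("exponential fitting is exact on its own model class", {
  tw <- seq(0, 3, by = 0.2)
  trace <- data.frame(waiting_time = tw,
                      magnitude = 2.0 * (1 - exp(-tw / 1.0)))
  k <- fit_exchange(trace)
  expect_lt(abs(k$tau_forward - 1.0), 1e-8)
  expect_lt(abs(k$amplitude - 2.0), 1e-8)
})

test_that("degenerate traces are rejected with diagnostics", {
  tw <- seq(0, 3, by = 0.5)
  expect_error(fit_exchange(data.frame(waiting_time = tw,
                                       magnitude = rep(1.3, length(tw)))),
               "bound|unidentifiable")
  expect_error(fit_exchange(data.frame(waiting_time = c(0, 1, 2),
                                       magnitude = c(0, 1, 1))),
               "4 waiting times")
})

test_that("changing vibrational lifetimes barely moves the fitted rate", {
  tau_ref <- exchange_protocol(simulate_2dir_series(
    exchange_gen_params(t1_shb = 0.67, t1_whb = 0.72)))$kinetics$tau_forward
  tau_alt <- exchange_protocol(simulate_2dir_series(
    exchange_gen_params(t1_shb = 0.4, t1_whb = 1.1)))$kinetics$tau_forward
  expect_lt(abs(tau_alt / tau_ref - 1), 0.02)
})

test_that("the whole extraction is invariant to a global intensity scale", {
  s <- simulate_2dir_series(exchange_gen_params())
  pr1 <- exchange_protocol(s)
  s$matrices <- lapply(s$matrices, function(m) 0.0042 * m)
  pr2 <- exchange_protocol(s)
  expect_equal(pr2$kinetics$tau_forward, pr1$kinetics$tau_forward,
               tolerance = 1e-10)
})

test_that("Arrhenius regression inverts exactly generated rates", {
  tk <- c(290, 310, 330, 355)
  k <- 12 * exp(-10 * 1000 / (R_GAS * tk))
  ar <- arrhenius_fit(tk, k)
  expect_equal(ar$Ea, 10, tolerance = 1e-10)
  expect_equal(exp(ar$ln_prefactor), 12, tolerance = 1e-9)
  flat <- arrhenius_fit(tk, rep(2.5, 4))
  expect_equal(flat$Ea, 0, tolerance = 1e-12)
  expect_error(arrhenius_fit(tk[1:2], k[1:2]), "3 points")
  expect_error(arrhenius_fit(tk, -k), "positive")
})

test_that("detailed balance round-trips the free energy", {
  expect_equal(reverse_rate(1.5, 0, 300), 1.5)
  kf <- 1 / 0.53
  kr <- reverse_rate(kf, 1.68, 296.15)
  dg_back <- -R_GAS * 296.15 * log(kf / kr) / 1000
  expect_equal(dg_back, 1.68, tolerance = 1e-12)
  expect_error(reverse_rate(1, 1, -5), "positive")
})
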
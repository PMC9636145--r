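# Photodiode model, network solver and the coupled time integration.

test_that("photocurrent and the safety bookkeeping reproduce the printed arithmetic", {
  lay <- build_hex_array(40, 300)
  pp <- pixel_params(lay)
  # 0.51 A/W x 0.1 W/cm^2 x 5.09e-6 cm^2
  expect_equal(photocurrent(1, pp), 0.51 * 0.1 * 2 * pi * (9e-4)^2, tolerance = 1e-12)
  expect_equal(photocurrent(1, pp) * 1e6, 0.26, tolerance = 0.01)
  expect_equal(photocurrent(0, pp), 0)
  expect_error(photocurrent(-1, pp), "nonnegative")

  pc <- pulse_charge(1.2, 10, pp)
  expect_equal(pc$charge_density_mC_cm2, 1.2, tolerance = 0.03)
  expect_equal(pc$voltage_step_V, 0.2, tolerance = 0.03)
})

test_that("diode law: zero at zero bias, knee near 0.5 V, convex in forward bias", {
  d <- diode_params()
  expect_equal(diode_dark_current(0, d), 0)
  # direct evaluation of the default calibration at the knee
  expect_equal(diode_dark_current(0.5, d),
               1.2e-12 * expm1(0.5 / (1.5 * 25.85e-3)), tolerance = 1e-12)
  expect_gt(diode_dark_current(0.5, d), 0.3e-6)
  expect_lt(diode_dark_current(0.5, d), 0.7e-6)
  v <- seq(0, 0.6, by = 0.02)
  iv <- diode_dark_current(v, d)
  expect_true(all(diff(iv) > 0))
  expect_true(all(diff(diff(iv)) > 0))
})

test_that("open-circuit photovoltage stays clamped by the single diode", {
  lay <- build_hex_array(40, 300)
  pp <- pixel_params(lay)
  voc <- open_circuit_voltage(8, pp)
  expect_lt(voc, 0.6)
  expect_gt(voc, 0.4)
  # monotone but logarithmic in irradiance
  expect_lt(open_circuit_voltage(16, pp) - voc, 0.05)
})

test_that("network solver: dark array carries no current, symmetry gives equal currents", {
  fx <- cluster7()
  n <- n_pixels(fx$layout)
  sol0 <- solve_network_currents(rep(0, n), 0, fx$rmat, fx$params)
  expect_equal(sol0$I, rep(0, n))

  solF <- solve_network_currents(rep(0, n), 1, fx$rmat, fx$params)
  outer6 <- which(rowSums(fx$layout$centers^2) > 1)
  expect_lt(diff(range(solF$I[outer6])) / max(abs(solF$I)), 1e-9)
  expect_lt(solF$residual, 1e-12)
})

test_that("a pre-charged dark centre pixel sinks current from its lit neighbours", {
  fx <- cluster7()
  centre <- which.min(rowSums(fx$layout$centers^2))
  irr <- rep(1, 7); irr[centre] <- 0
  u <- rep(0, 7); u[centre] <- 0.5
  sol <- solve_network_currents(u, irr, fx$rmat, fx$params)
  expect_lt(sol$I[centre], 0)                       # cathodic transient return
  expect_true(all(sol$I[-centre] > 0))

  # at 0.2 V the dark pixel is essentially non-conductive
  u2 <- rep(0, 7); u2[centre] <- 0.2
  sol2 <- solve_network_currents(u2, irr, fx$rmat, fx$params)
  expect_lt(abs(sol2$I[centre]), 0.05 * max(sol2$I))
})

test_that("precondition sets exactly the requested interfaces and is idempotent", {
  fx <- cluster7()
  st <- initial_state(fx$layout)
  st2 <- precondition(st, c(2, 5), 0.5)
  expect_equal(st2$u, c(0, 0.5, 0, 0, 0.5, 0, 0))
  expect_identical(precondition(st2, c(2, 5), 0.5), st2)
  expect_error(precondition(st, 99, 0.5), "unknown pixel index")
  expect_error(precondition(st, 1, 1.5), "within")
})

test_that("zero light keeps a discharged array at rest and charge is conserved", {
  fx <- cluster7()
  drv <- project_pattern(fx$layout, pattern_full_field(), 0, 10, 40, duration = 25)
  tr <- simulate_array(drv, fx$rmat, fx$params)
  expect_lt(max(abs(tr$u)), 1e-15)
  expect_lt(max(abs(tr$I)), 1e-15)

  drv8 <- project_pattern(fx$layout, pattern_full_field(), 8, 10, 40, duration = 25)
  tr8 <- simulate_array(drv8, fx$rmat, fx$params)
  expect_lt(max(abs(rowSums(tr8$I) + tr8$I_return)), 1e-18)
})

test_that("interface charge bookkeeping: C du equals the integrated current", {
  fx <- cluster7()
  drv <- project_pattern(fx$layout, pattern_full_field(), 8, 10, 40, duration = 10)
  tr <- simulate_array(drv, fx$rmat, fx$params, dt_out = 0.005)
  k <- length(tr$t)
  du <- tr$u[k, 1] - tr$u[1, 1]
  q <- sum((tr$I[-1, 1] + tr$I[-k, 1]) / 2 * diff(tr$t)) * 1e-3
  expect_lt(abs(fx$params$C_active * du - q) / abs(q), 1e-3)
})

test_that("adaptive integrator agrees with a 1 us implicit-Euler oracle within 1% RMS", {
  fx <- cluster7()
  drv <- project_pattern(fx$layout, pattern_full_field(), 8, 10, 40, duration = 25)
  tr <- simulate_array(drv, fx$rmat, fx$params, dt_out = 0.05)
  orc <- simulate_array(drv, fx$rmat, fx$params, dt_out = 0.05, dt_fixed = 0.001)
  expect_lt(sqrt(mean((tr$u - orc$u)^2)) / sqrt(mean(orc$u^2)), 0.01)
  expect_lt(sqrt(mean((tr$I - orc$I)^2)) / sqrt(mean(orc$I^2)), 0.01)
})

test_that("periodic steady state balances charge and deepens bias with repetition rate", {
  fx <- cluster7()
  dark <- project_pattern(fx$layout, pattern_full_field(), 0, 10, 40, duration = 25)
  tr0 <- run_to_steady_state(dark, fx$rmat, fx$params)
  expect_equal(attr(tr0, "periods"), 1L)

  pre <- vapply(c(10, 20, 40), function(rt) {
    d <- project_pattern(fx$layout, pattern_full_field(), 8, 10, rt,
                         duration = 1000 / rt)
    ss <- run_to_steady_state(d, fx$rmat, fx$params)
    # zero net charge through each interface over the period
    k <- nrow(ss$I)
    qnet <- sum((ss$I[-1, 1] + ss$I[-k, 1]) / 2 * diff(ss$t)) * 1e-3
    qpk <- max(abs(ss$I[, 1])) * 0.01
    expect_lt(abs(qnet), 0.01 * qpk)
    attr(ss, "state0")$u[1]
  }, numeric(1))
  expect_true(all(diff(pre) > 0))
})
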
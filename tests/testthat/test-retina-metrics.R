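# Field maps, trans-cellular stimulation steps, grating contrast, far field.

test_that("potential maps: zero currents vanish, one pixel reproduces its kernel", {
  fx <- cluster7()
  m0 <- potential_map(rep(0, 7), fx$rmat, z = 10)
  expect_true(all(m0$potential == 0))

  I <- rep(0, 7); centre <- which.min(rowSums(fx$layout$centers^2))
  I[centre] <- 1e-6
  xs <- c(0, 10, 25, 50)
  m1 <- potential_map(I, fx$rmat, z = 10, x = xs, y = 0)
  # independent kernel: quadrature disk potential plus the annular ring sink
  med <- fx$rmat$medium
  want <- vapply(xs, function(x) disk_potential(9, med, c(x, 0, 10)), numeric(1)) * 1e-6 -
    1e-6 * pvpix:::annulus_pot(xs * 1e-6, 10e-6,
                               fx$layout$return_inner * 1e-6,
                               fx$layout$return_outer * 1e-6,
                               pvpix:::medium_si(med))
  expect_rel(drop(m1$potential), want, 2e-3)
  expect_error(potential_map(I, fx$rmat, z = -5), "out of domain")
})

test_that("trans-cellular step is positive over an active pixel and vanishes far away", {
  fx <- cluster7()
  I <- rep(0, 7); centre <- which.min(rowSums(fx$layout$centers^2))
  I[centre] <- 1e-6
  st <- transcellular_step(I, fx$rmat)
  expect_gt(st$step[centre], 0)
  expect_gt(st$step[centre], max(st$step[-centre]))

  # both planes converge far from the array: step collapses relative to near field
  far <- superpose_at_test(fx$rmat, cbind(20000, 0), 10, I) -
    superpose_at_test(fx$rmat, cbind(20000, 0), 57, I)
  expect_lt(abs(far), 1e-3 * st$step[centre])
})

test_that("grating contrast: flat fields give zero, preconditioning flips dark rows negative", {
  fx <- array_mid()
  lay <- fx$layout
  pat <- pattern_grating(lay$row_pitch)
  # identical potentials everywhere -> zero contrast under both definitions
  flat <- grating_contrast(rep(1e-3, n_pixels(lay)), pat, lay)
  expect_equal(flat$contrast, 0)
  expect_equal(flat$modulation, 0)

  bright <- pattern_weights(pat, lay) > 0.5
  run <- function(bias, role) {
    u <- ifelse(bright, 0, bias)
    sol <- solve_network_currents(u, ifelse(bright, 1, 0), fx$rmat, fx$params,
                                  conducting = if (role == "off") bright else NULL)
    grating_contrast(transcellular_step(sol$I, fx$rmat), pat, lay)
  }
  weak <- run(0.2, "off")
  strong <- run(0.5, "net")
  expect_lt(strong$dark_mean_mV, 0)         # transient returns drive rows negative
  expect_gte(strong$contrast, 100)
  expect_gt(strong$contrast, weak$contrast) # the preconditioning mechanism, strictly
  expect_gt(weak$contrast, 0)

  tiny <- build_hex_array(40, 120)
  expect_error(grating_contrast(rep(1, 7), pattern_grating(tiny$row_pitch), tiny),
               "insufficient geometry")
})

test_that("far-field waveform is biphasic for a full-field pulse and zero without current", {
  fx <- cluster7()
  drv <- project_pattern(fx$layout, pattern_full_field(), 8, 4, 5, duration = 200)
  tr <- run_to_steady_state(drv, fx$rmat, fx$params)
  ff <- far_field_waveform(tr)
  expect_gt(max(ff$v[ff$t_ms < 4]), 0)              # anodic during the pulse
  expect_lt(min(ff$v[ff$t_ms > 4]), 0)              # cathodic recovery after
  expect_gt(max(ff$v), -min(ff$v))

  trz <- simulate_array(project_pattern(fx$layout, pattern_full_field(), 0, 4, 5,
                                        duration = 50),
                        fx$rmat, fx$params)
  expect_true(all(far_field_waveform(trz)$v == 0))
  expect_error(frequency_sweep(numeric(0), fx$layout, fx$rmat, fx$params),
               "empty rate")
})

test_that("peak_to_peak windows behave", {
  df <- data.frame(t_ms = 0:10, v = c(0, 2, -1, rep(0, 8)))
  expect_equal(peak_to_peak(df), 3)
  expect_equal(peak_to_peak(df, c(3, 10)), 0)
  expect_error(peak_to_peak(df, c(20, 30)), "empty window")
})
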
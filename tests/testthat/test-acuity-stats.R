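# The acuity pipeline: artifact removal, spectral cleaning, amplitudes,
# noise floor and the log-fit/noise-intersection estimator.

test_that("template subtraction removes scaled artifacts and spares orthogonal signal", {
  set.seed(1)
  tpl <- sin(seq(0, 20 * pi, length.out = 2000))
  expect_lt(max(abs(remove_artifact(3 * tpl, tpl))), 1e-12)
  orth <- cos(seq(0, 20 * pi, length.out = 2000))   # orthogonal on full periods
  expect_equal(remove_artifact(orth, tpl), orth, tolerance = 1e-9)
  expect_error(remove_artifact(orth, rep(0, 2000)), "zero norm")
  expect_error(remove_artifact(orth, tpl[-1]), "equal length")

  # synthetic recording with a known artifact: residual artifact power < 1%
  g <- vep_generator_params(trial_noise_sd = 0, animal_sd = 0, noise_floor_sd = 0)
  vs <- synth_recording(g, 78, n_animals = 1, seed = 2)
  rec <- vs$recordings[[1]]
  art <- pvpix:::carrier_artifact(rec$t_ms, g$carrier, g$pulse_width, 1)
  cleaned <- remove_artifact(rec$trace, art)
  pure_art <- g$artifact_uV * art
  resid_power <- sum((cleaned - (rec$trace - pure_art))^2)
  expect_lt(resid_power, 0.01 * sum(pure_art^2))
})

test_that("spectral cleaning notches the carrier but passes the reversal band", {
  fs <- 2000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs) * 1000
  s2 <- sin(2 * pi * 2 * t / 1000)
  s64 <- sin(2 * pi * 64 * t / 1000)
  out2 <- spectral_clean(s2, fs, 64)
  expect_lt(max(abs(out2 - s2)) / max(abs(s2)), 0.01)
  out64 <- spectral_clean(s64, fs, 64)
  expect_lt(max(abs(out64)) / max(abs(s64)), 0.01)   # > 40 dB attenuation
  mixed <- 5 * s2 + 20 * s64 + 3 * sin(2 * pi * 128 * t / 1000)
  outm <- spectral_clean(mixed, fs, 64)
  amp2 <- 2 * abs(fft(outm)[which.min(abs((seq_along(t) - 1) * fs / length(t) - 2))]) /
    length(t)
  expect_equal(amp2, 5, tolerance = 0.02)
  expect_error(spectral_clean(s2, fs, carrier = 1200), "Nyquist")
  expect_error(spectral_clean(s2[1:30], fs, 64), "shorter")
})

test_that("reversal amplitude is the windowed range averaged over reversals", {
  fs <- 2000
  flat <- rep(0, 4 * fs)
  expect_equal(reversal_amplitude(flat, fs), 0)
  tr <- rep(0, 4 * fs)
  # one excursion per 500 ms epoch inside the 0-100 ms window
  for (k in 0:7) {
    tr[k * 1000 + 50] <- 7     # +b at 24.5 ms
    tr[k * 1000 + 120] <- -3   # -a at 59.5 ms
  }
  expect_equal(reversal_amplitude(tr, fs), 10)
  expect_error(reversal_amplitude(flat, fs, window = c(50, 50)), "empty window")
  expect_error(reversal_amplitude(flat, fs, window = c(0, 600)), "fit")
})

test_that("noise floor: silent recordings give zero; Gaussian traces match the range statistic", {
  g0 <- vep_generator_params(trial_noise_sd = 0, animal_sd = 0, noise_floor_sd = 0)
  vs0 <- synth_recording(g0, rep(Inf, 3), n_animals = 2, seed = 5)
  nf0 <- noise_floor(vs0)
  expect_equal(nf0$mean, 0, tolerance = 1e-12)
  expect_equal(nf0$sd, 0, tolerance = 1e-12)

  # brute-force oracle for E[max - min] of the windowed Gaussian
  set.seed(77)
  sim <- replicate(4000, { x <- rnorm(200); max(x) - min(x) })
  sigma <- 1.3
  traces <- replicate(60, {
    tr <- rnorm(4 * 2000, 0, sigma)
    reversal_amplitude(tr, 2000)
  })
  # each measured value averages 8 windows; compare means
  expect_equal(mean(traces), sigma * mean(sim), tolerance = 0.02 * sigma * mean(sim))
  expect_error(noise_floor(1), "at least 2")
})

test_that("the acuity fit inverts a noiseless log-line exactly and flags degenerate input", {
  # A = 50 - 10 ln(s/s0) with s0 = 1/100; noise mean 10
  s0 <- 1 / 100
  bw <- c(150, 100, 60, 40, 25)
  amps <- data.frame(bar_width = rep(bw, each = 2),
                     amplitude = rep(50 - 10 * log((1 / bw) / s0), each = 2))
  nf <- noise_floor(rep(10, 4))
  est <- suppressWarnings(fit_acuity(amps, nf))
  # closed form: ln s* = (10 - beta0)/beta1 with beta0 = 50 + 10 ln s0
  want <- 1 / (s0 * exp((10 - 50) / -10))
  expect_equal(est$acuity_um, want, tolerance = 1e-9)
  expect_equal(est$sd_um, 0, tolerance = 1e-9)

  low <- data.frame(bar_width = rep(bw, each = 2), amplitude = 1)
  expect_error(suppressWarnings(fit_acuity(low, noise_floor(c(10, 10.5, 9.5)))),
               "estimation impossible")
  set.seed(4)
  rising <- data.frame(bar_width = rep(bw, each = 3),
                       amplitude = rep(c(20, 25, 30, 35, 40), each = 3) +
                         rnorm(15, 0, 0.1))
  expect_error(fit_acuity(rising, noise_floor(c(1, 1.2, 0.8))), "no decline")
})

test_that("a higher noise floor yields a coarser acuity, monotonically", {
  g <- vep_generator_params()
  d <- synth_amplitudes(g, c(157, 104, 78, 52, 39), n_animals = 6, seed = 31)
  ests <- vapply(c(6, 9, 12), function(m) {
    nf <- structure(list(mean = m, sd = 1, n = 8, values = rep(m, 8)),
                    class = "pv_noise_floor")
    fit_acuity(d$amplitudes, nf)$acuity_um
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("unit conversion matches the printed anchors and round-trips", {
  expect_equal(bar_width_to_cpd(27.9), 1.15, tolerance = 0.005)
  expect_equal(bar_width_to_cpd(32.15), 1.000, tolerance = 1e-4)
  expect_equal(cpd_to_bar_width(bar_width_to_cpd(41.7)), 41.7, tolerance = 1e-12)
  expect_error(bar_width_to_cpd(-1), "positive")
  v <- bar_width_to_cpd(27.9, factor_sd = 2.9)
  expect_equal(attr(v, "sd"), 2.9 / (2 * 27.9), tolerance = 1e-12)
})
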
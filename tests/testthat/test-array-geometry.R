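# Hexagonal layout construction and optical pattern projection.

test_that("hexagonal lattice has the advertised pitch and neighbour geometry", {
  lay40 <- build_hex_array(40, 1500, 18)
  expect_equal(lay40$row_pitch, 40 * cos(pi / 6), tolerance = 1e-12)
  expect_equal(round(lay40$row_pitch, 1), 34.6)
  lay20 <- build_hex_array(20, 1500, 9)
  expect_equal(round(lay20$row_pitch, 1), 17.3)

  # every centre within the disc
  r <- sqrt(rowSums(lay40$centers^2))
  expect_true(all(r <= 750 + 1e-9))

  # nearest-neighbour distance equals the pixel width (relative 1e-9)
  sub <- lay40$centers[r < 300, ]
  dn <- as.matrix(dist(sub)); diag(dn) <- Inf
  expect_equal(min(dn), 40, tolerance = 1e-9)

  # degenerate disc: single pixel at the origin
  lay1 <- build_hex_array(40, 40, 18)
  expect_equal(n_pixels(lay1), 1L)
  expect_equal(unname(lay1$centers[1, ]), c(0, 0))

  expect_error(build_hex_array(40, 1500, 45), "invalid geometry")
})

test_that("pixel count matches a brute-force lattice enumeration", {
  lay <- build_hex_array(40, 1500, 18)
  # independent oracle: enumerate an over-large integer lattice, clip to disc
  rp <- 40 * cos(pi / 6)
  cnt <- 0L
  for (k in -30:30) {
    y <- k * rp
    xo <- if (k %% 2 == 0) 0 else 20
    for (i in -30:30) {
      x <- i * 40 + xo
      if (x^2 + y^2 <= 750^2 + 1e-9) cnt <- cnt + 1L
    }
  }
  expect_equal(n_pixels(lay), cnt)
  expect_lt(abs(n_pixels(lay) - 1275) / 1275, 0.02)
})

test_that("lattice is translation-consistent along a lattice vector", {
  lay <- build_hex_array(40, 800)
  key <- function(m) paste(round(m[, 1], 6), round(m[, 2], 6))
  all_keys <- key(lay$centers)
  inner <- sqrt(rowSums(lay$centers^2)) <= 400 - 45
  shifted <- lay$centers[inner, , drop = FALSE]
  shifted[, 1] <- shifted[, 1] + 40
  expect_true(all(key(shifted) %in% all_keys))
})

test_that("gratings aligned to the row pitch light alternating rows and reverse cleanly", {
  lay <- build_hex_array(40, 600)
  g <- pattern_grating(bar_width = lay$row_pitch)
  w1 <- pattern_weights(g, lay, frame = 1)
  w2 <- pattern_weights(g, lay, frame = 2)
  even <- lay$row_index %% 2 == 0
  expect_equal(w1, as.numeric(even))
  expect_equal(w2, as.numeric(!even))

  # reversal conserves the illuminated count over the interior (edge effects
  # only at the rim)
  interior <- sqrt(rowSums(lay$centers^2)) < 300 - 2 * lay$row_pitch
  expect_lt(abs(sum(w1[interior]) - sum(w2[interior])), 0.05 * sum(w1[interior]))

  expect_true(all(pattern_weights(pattern_full_field(), lay) == 1))
})

test_that("octagonal field stop illuminates the expected pixel fraction", {
  lay <- build_hex_array(40, 1500)
  w <- 1000
  frac <- mean(pattern_weights(pattern_field_stop(w), lay))
  # Monte-Carlo point-in-polygon oracle over the device disc
  set.seed(101)
  th <- runif(2e5, 0, 2 * pi); rr <- 750 * sqrt(runif(2e5))
  px <- rr * cos(th); py <- rr * sin(th)
  inside <- abs(px) <= w / 2 & abs(py) <= w / 2 & abs(px) + abs(py) <= w / sqrt(2)
  # agreement to about one pixel row at the octagon boundary
  expect_lt(abs(frac - mean(inside)), 40 / w)
  # closed-form octagon area as a second reference
  expect_lt(abs(frac - 2 * (sqrt(2) - 1) * w^2 / (pi * 750^2)), 40 / w)
})

test_that("project_pattern gates irradiance by the pulse train and reverses gratings", {
  lay <- build_hex_array(40, 300)
  drv <- project_pattern(lay, pattern_full_field(), 8, pulse_width = 10,
                         rate = 40, duration = 100)
  expect_equal(drive_irradiance(drv, 5), rep(8, n_pixels(lay)))
  expect_equal(drive_irradiance(drv, 15), rep(0, n_pixels(lay)))
  expect_true(all(drive_irradiance(drv, seq(0, 99, by = 0.5)) >= 0))

  # linear in peak irradiance
  drv2 <- project_pattern(lay, pattern_full_field(), 16, 10, 40, duration = 100)
  expect_equal(drive_irradiance(drv2, 5), 2 * drive_irradiance(drv, 5))

  g <- pattern_grating(lay$row_pitch)
  dg <- project_pattern(lay, g, 1, 4, 64, reversal_period = 500, duration = 1000)
  even <- lay$row_index %% 2 == 0
  expect_equal(drive_irradiance(dg, 1) > 0, even)
  expect_equal(drive_irradiance(dg, 501) > 0, !even)

  expect_error(project_pattern(lay, g, 1, pulse_width = 30, rate = 40),
               "invalid timing")
})

test_that("layout CSV round-trips", {
  lay <- build_hex_array(20, 300)
  f <- tempfile(fileext = ".csv")
  write_layout_csv(lay, f)
  lay2 <- read_layout_csv(f)
  expect_equal(lay2$centers[, 1], lay$centers[, 1])
  expect_equal(lay2$pixel_width, 20)
  expect_equal(lay2$return_outer, lay$return_outer)
  unlink(f)
})
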
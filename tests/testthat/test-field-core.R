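# Disk-electrode potentials, access resistances and cross-resistance matrices.

test_that("UCD disk potential matches an independent quadrature of the point-source kernel", {
  med <- medium(100)   # 1 ohm m
  a <- 9; rho <- 1
  # oracle: polar double integral of rho/(2 pi r) over the disk
  oracle <- function(r_um, z_um) {
    a_m <- a * 1e-6; J <- 1 / (pi * a_m^2)
    f_s <- function(s) {
      vapply(s, function(si) {
        g <- function(th) 1 / sqrt((r_um * 1e-6)^2 + si^2 -
                                     2 * r_um * 1e-6 * si * cos(th) + (z_um * 1e-6)^2)
        si * integrate(g, 0, 2 * pi, rel.tol = 1e-10)$value
      }, numeric(1))
    }
    rho * J / (2 * pi) * integrate(f_s, 0, a_m, rel.tol = 1e-8)$value
  }
  pts <- rbind(c(0, 0, 0), c(0, 0, 5), c(4, 0, 3), c(20, 0, 0), c(15, 5, 10))
  got <- disk_potential(a, med, pts)
  want <- apply(pts, 1, function(p) oracle(sqrt(p[1]^2 + p[2]^2), p[3]))
  expect_rel(got, want, 1e-4)

  # printed anchors: rho I/(pi a) on axis, point-source far field at 1 mm
  expect_equal(disk_potential(a, med, c(0, 0, 0)) * 1e-6, 0.0354, tolerance = 1e-3)
  expect_equal(disk_potential(a, med, c(0, 0, 1000)) * 1e-6, 1 / (2 * pi * 1e-3) * 1e-6,
               tolerance = 1e-3)

  # strictly decreasing along the axis
  zs <- seq(0, 200, by = 5)
  vz <- disk_potential(a, med, cbind(0, 0, zs))
  expect_true(all(diff(vz) < 0))

  expect_error(disk_potential(a, med, c(0, 0, -1)), "out of domain")
})

test_that("access resistances reproduce the closed forms and scale with resistivity", {
  med <- medium(100)
  expect_equal(access_resistance(9, med, "EP"), 1 / (4 * 9e-6), tolerance = 1e-12)
  expect_equal(access_resistance(9, med, "UCD"), 8 / (3 * pi^2 * 9e-6),
               tolerance = 1e-12)
  # UCD value against an independent disk-average of the disk potential
  avg <- local({
    f <- function(r_um) {
      vapply(r_um, function(r) disk_potential(9, med, c(r, 0, 0)), numeric(1)) *
        2 * pi * r_um
    }
    integrate(f, 0, 9, rel.tol = 1e-7)$value / (pi * 81)
  })
  expect_rel(access_resistance(9, med, "UCD"), avg, 1e-4)
  expect_equal(round(access_resistance(9, med, "UCD") / 1e3, 2), 30.02)
  expect_equal(round(access_resistance(9, med, "EP") / 1e3, 2), 27.78)

  expect_equal(access_resistance(9, medium(200), "EP"),
               2 * access_resistance(9, medium(100), "EP"), tolerance = 1e-12)
  expect_equal(access_resistance(9, medium(200), "UCD"),
               2 * access_resistance(9, medium(100), "UCD"), tolerance = 1e-12)
})

test_that("pairwise coupling of two isolated disks approaches rho/(2 pi d)", {
  lay <- pair_layout(d_um = 40, a_um = 9)
  rm_ <- cross_resistance_matrix(lay, medium(700))
  point <- 7 / (2 * pi * 40e-6)
  # ring is 2 cm away, so its terms are negligible; disk-averaging < 3%
  expect_lt(abs(rm_$R[1, 2] - point) / point, 0.03)
  expect_equal(rm_$R[1, 2] / 1e3, 27.9, tolerance = 0.03)
})

test_that("cross-resistance matrices are reciprocal with dominant diagonals and monotone decay", {
  for (dia in c(200, 340)) {
    lay <- build_hex_array(40, dia)
    rm_ <- cross_resistance_matrix(lay, medium())
    R <- rm_$R
    expect_lt(max(abs(R - t(R))) / max(R), 1e-6)
    expect_true(all(diag(R) > 0))
    expect_true(all(diag(R) > apply(R - diag(diag(R)), 1, max)))
  }
  # off-diagonals decrease with centre distance for interior pixel pairs
  # (distance-shell means; ring terms vary slightly within a shell)
  lay <- build_hex_array(40, 600)
  rm_ <- cross_resistance_matrix(lay, medium())
  centre <- which.min(rowSums(lay$centers^2))
  interior <- sqrt(rowSums(lay$centers^2)) < 300 - 2 * lay$row_pitch
  j <- which(interior & seq_len(n_pixels(lay)) != centre)
  shell <- round(rm_$distances[centre, j], 9)
  mu <- tapply(rm_$R[centre, j], shell, mean)
  expect_true(all(diff(mu[order(as.numeric(names(mu)))]) < 1e-9))

  expect_error(cross_resistance_matrix(pair_layout(d_um = 10, a_um = 9), medium()),
               "overlap")
})

test_that("layered media reduce long-range couplings without touching short range much", {
  hom <- cross_resistance_matrix(build_hex_array(40, 400), medium(700))
  layd <- cross_resistance_matrix(build_hex_array(40, 400), tissue_medium())
  d <- hom$distances; diag(d) <- Inf
  far <- d > 250e-6
  # the conductive vitreous above can only pull potentials down
  expect_true(all(layd$kernel_matrix < hom$kernel_matrix))
  expect_lt(mean(layd$kernel_matrix[far]), 0.9 * mean(hom$kernel_matrix[far]))
})

test_that("field superposition is linear to near machine precision", {
  fx <- cluster7()
  set.seed(5)
  I1 <- runif(7) * 1e-6; I2 <- runif(7) * 1e-6
  m1 <- potential_map(I1, fx$rmat, z = 10, x = seq(-60, 60, 20), y = 0)
  m2 <- potential_map(I2, fx$rmat, z = 10, x = seq(-60, 60, 20), y = 0)
  m12 <- potential_map(2 * I1 + 3 * I2, fx$rmat, z = 10, x = seq(-60, 60, 20), y = 0)
  expect_lt(max(abs(m12$potential - 2 * m1$potential - 3 * m2$potential)) /
              max(abs(m12$potential)), 1e-10)
})
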
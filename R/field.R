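#' Conductive medium above the implant
#'
#' The implant face is an insulating plane at z = 0; tissue or electrolyte
#' occupies z > 0. The default is a homogeneous half-space. Setting
#' `layer_thickness` stacks a finite layer of resistivity `resistivity`
#' (the retina) on top of the implant with a second half-space of resistivity
#' `resistivity_above` (the vitreous) above it; potentials are then computed
#' by a method-of-images reflection series.
#'
#' @param resistivity Resistivity of the medium (or of the retinal layer),
#'   ohm-cm. The default 700 ohm-cm matches both retinal tissue and
#'   phosphate-buffered saline diluted to 10 percent by volume.
#' @param layer_thickness Retina layer thickness, um, or `NULL` for a
#'   homogeneous half-space.
#' @param resistivity_above Resistivity of the half-space above the layer,
#'   ohm-cm (used only when `layer_thickness` is set).
#' @param description Free-text label.
#' @return A `pv_medium` object.
#' @examples
#' medium()                                   # homogeneous, 700 ohm-cm
#' medium(700, layer_thickness = 90,
#'        resistivity_above = 55)             # retina over vitreous
#' @export
medium <- function(resistivity = 700, layer_thickness = NULL,
                   resistivity_above = 55,
                   description = if (is.null(layer_thickness))
                     "homogeneous half-space" else "retina layer over vitreous") {
  if (resistivity <= 0) stop("resistivity must be positive")
  if (!is.null(layer_thickness)) {
    stopifnot(layer_thickness > 0, resistivity_above > 0)
  }
  structure(list(resistivity = resistivity,
                 layer_thickness = layer_thickness,
                 resistivity_above = resistivity_above,
                 description = description), class = "pv_medium")
}

#' Retina-over-vitreous tissue medium
#'
#' Convenience constructor for the subretinal stimulation geometry: a
#' resistive inner-retina layer on the insulating implant, bounded above by
#' the much better conducting vitreous.
#'
#' @param retina_resistivity Retinal resistivity, ohm-cm.
#' @param retina_thickness Degenerate inner-retina thickness, um.
#' @param vitreous_resistivity Vitreous resistivity, ohm-cm.
#' @return A `pv_medium`.
#' @export
tissue_medium <- function(retina_resistivity = 700, retina_thickness = 90,
                          vitreous_resistivity = 55) {
  medium(retina_resistivity, layer_thickness = retina_thickness,
         resistivity_above = vitreous_resistivity,
         description = "degenerate retina over vitreous")
}

#' @export
print.pv_medium <- function(x, ...) {
  cat(sprintf("<pv_medium> %s: %g ohm-cm", x$description, x$resistivity))
  if (!is.null(x$layer_thickness))
    cat(sprintf(", %g um layer over %g ohm-cm", x$layer_thickness, x$resistivity_above))
  cat("\n")
  invisible(x)
}

# ---- internal kernels (SI units: metres, ohms) ------------------------------

# medium in SI: rho (ohm m), Tlay (m or NULL), kref reflection coefficient
medium_si <- function(med) {
  rho <- med$resistivity * 1e-2
  if (is.null(med$layer_thickness)) {
    list(rho = rho, Tlay = NULL, kref = 0, nimg = 0L)
  } else {
    rho2 <- med$resistivity_above * 1e-2
    kref <- (rho2 - rho) / (rho2 + rho)
    # truncate the reflection series when |kref|^n < 1e-6
    nimg <- if (abs(kref) < 1e-12) 0L else
      min(200L, max(10L, ceiling(log(1e-6) / log(abs(kref)))))
    list(rho = rho, Tlay = med$layer_thickness * 1e-6, kref = kref, nimg = nimg)
  }
}

# elliptic K with the pracma parameter convention m = k^2, guarded near m = 1
ellipK <- function(m) {
  m <- pmin(pmax(m, 0), 1 - 1e-15)
  pracma::ellipke(m)$k
}

# potential of a uniform-current-density disk (radius a) on the insulating
# plane, at lateral distance r and height z, per ampere, homogeneous medium.
# Vectorized over r (scalar z).
ucd_disk_pot <- function(r, z, a, rho) {
  J <- 1 / (pi * a^2)
  vapply(r, function(ri) {
    if (ri < 1e-15 * max(a, 1e-9)) return(rho * J * (sqrt(a^2 + z^2) - z))
    f <- function(s) {
      m <- 4 * ri * s / ((ri + s)^2 + z^2)
      s * 4 / sqrt((ri + s)^2 + z^2) * ellipK(m)
    }
    v <- if (z < a / 5 && ri < a) {
      integrate(f, 0, ri, rel.tol = 1e-9)$value +
        integrate(f, ri, a, rel.tol = 1e-9)$value
    } else {
      integrate(f, 0, a, rel.tol = 1e-9)$value
    }
    rho * J / (2 * pi) * v
  }, numeric(1))
}

# potential of an equipotential disk electrode passing current I = 1 A,
# homogeneous half-space (classical charged-disk solution)
ep_disk_pot <- function(r, z, a, rho) {
  v0 <- rho / (4 * a)
  den <- sqrt((r - a)^2 + z^2) + sqrt((r + a)^2 + z^2)
  v0 * (2 / pi) * asin(pmin(2 * a / den, 1))
}

# thin current ring of radius b on the plane, unit total current
ring_pot_si <- function(r, z, b, rho) {
  m <- 4 * r * b / ((r + b)^2 + z^2)
  rho * ellipK(m) / (pi^2 * sqrt((r + b)^2 + z^2))
}

# layered-medium image correction for a compact source at the origin plane,
# treated as a point at distance r, height z (valid for image distances >> a)
layer_image_point <- function(r, z, ms) {
  if (ms$nimg == 0L) return(rep(0, length(r)))
  n <- seq_len(ms$nimg)
  kn <- ms$kref^n
  out <- numeric(length(r))
  for (i in seq_along(r)) {
    out[i] <- sum(kn * ms$rho / (2 * pi) *
                    (1 / sqrt(r[i]^2 + (2 * n * ms$Tlay - z)^2) +
                     1 / sqrt(r[i]^2 + (2 * n * ms$Tlay + z)^2)))
  }
  out
}

# same for a ring source of radius b (images are rings at heights 2nT -/+ z)
layer_image_ring <- function(r, z, b, ms) {
  if (ms$nimg == 0L) return(rep(0, length(r)))
  n <- seq_len(ms$nimg)
  kn <- ms$kref^n
  out <- numeric(length(r))
  for (i in seq_along(r)) {
    out[i] <- sum(kn * (ring_pot_si(r[i], 2 * n * ms$Tlay - z, b, ms$rho) +
                        ring_pot_si(r[i], 2 * n * ms$Tlay + z, b, ms$rho)))
  }
  out
}

# ---- exported field operations ---------------------------------------------

#' Potential of a disk electrode in the medium
#'
#' Quasi-static potential generated by a single disk electrode of radius
#' `electrode_radius` centred at the origin of the insulating plane, per
#' ampere of injected current. UCD (uniform current density) is the boundary
#' condition appropriate for pulses much longer than the electrode's RC time;
#' EP (equipotential) for much shorter ones or for the large common return.
#' In a layered medium the reflection-series correction treats the disk as
#' compact relative to the layer thickness (image terms use the point kernel;
#' for the EP mode the same series is applied to the equipotential solution,
#' an approximation documented in the methods vignette).
#'
#' @param electrode_radius Disk radius, um.
#' @param medium A `pv_medium`.
#' @param point Numeric length-3 vector or n x 3 matrix `(x, y, z)` in um,
#'   z >= 0.
#' @param mode `"UCD"` or `"EP"`.
#' @return Potential(s) in volts per ampere (ohms).
#' @examples
#' disk_potential(9, medium(100), c(0, 0, 0))   # rho I / (pi a) on axis
#' @export
disk_potential <- function(electrode_radius, medium, point, mode = c("UCD", "EP")) {
  mode <- match.arg(mode)
  stopifnot(electrode_radius > 0, inherits(medium, "pv_medium"))
  if (is.null(dim(point))) point <- matrix(point, ncol = 3)
  if (any(point[, 3] < 0)) stop("out of domain: points must have z >= 0")
  ms <- medium_si(medium)
  a <- electrode_radius * 1e-6
  r <- sqrt(point[, 1]^2 + point[, 2]^2) * 1e-6
  z <- point[, 3] * 1e-6
  base <- vapply(seq_along(r), function(i) {
    if (mode == "UCD") ucd_disk_pot(r[i], z[i], a, ms$rho)
    else ep_disk_pot(r[i], z[i], a, ms$rho)
  }, numeric(1))
  img <- vapply(seq_along(r), function(i) layer_image_point(r[i], z[i], ms),
                numeric(1))
  base + img
}

#' Access resistance of a disk electrode
#'
#' The resistance between a disk electrode and a distant reference through the
#' volume conductor. EP mode gives the classical spreading resistance
#' rho/(4a); UCD mode gives the disk-averaged self potential of a uniform
#' current density disk, 8 rho / (3 pi^2 a). Linear in resistivity. Layer
#' images (if any) add the disk-averaged correction at zero height.
#'
#' @inheritParams disk_potential
#' @return Resistance, ohms.
#' @examples
#' access_resistance(9, medium(100), mode = "EP")   # rho/(4a) = 27.8 kOhm
#' @export
access_resistance <- function(electrode_radius, medium, mode = c("UCD", "EP")) {
  mode <- match.arg(mode)
  stopifnot(electrode_radius > 0)
  ms <- medium_si(medium)
  a <- electrode_radius * 1e-6
  base <- if (mode == "EP") ms$rho / (4 * a) else 8 * ms$rho / (3 * pi^2 * a)
  base + layer_image_point(0, 0, ms)
}

# disk-averaged potential produced at a coplanar disk (same radius a) whose
# centre is at distance d, per ampere of UCD current; homogeneous part only.
# 7-point average over the receiving disk (centre + ring at a/sqrt(2)).
ucd_mutual_hom <- function(d, a, rho) {
  if (d < 1e-15) return(8 * rho / (3 * pi^2 * a))
  s <- a / sqrt(2)
  th <- (0:5) * pi / 3
  rr <- c(d, sqrt(d^2 + s^2 + 2 * d * s * cos(th)))
  w <- c(0.25, rep(0.75 / 6, 6))
  sum(w * ucd_disk_pot(rr, 0, a, rho))
}

# radial interpolator for the UCD disk kernel at height z (SI), incl. images;
# beyond the spline range the disk is a point source (exact to O((a/d)^2))
ucd_kernel_spline <- function(a, z, ms, dmax) {
  dg <- unique(c(0, a / 2, a, seq(1.5 * a, 6 * a, by = a / 2),
                 seq(7 * a, dmax, length.out = 200)))
  v <- ucd_disk_pot(dg, z, a, ms$rho) + layer_image_point(dg, z, ms)
  sp <- splinefun(dg, v, method = "natural")
  function(d) {
    out <- sp(d)
    beyond <- d > dmax
    if (any(beyond)) {
      db <- d[beyond]
      out[beyond] <- ms$rho / (2 * pi * sqrt(db^2 + z^2)) +
        layer_image_point(db, z, ms)
    }
    out
  }
}

# uniformly distributed annular return sink: potentials and self resistance
annulus_pot <- function(r, z, b1, b2, ms, n_sub = 8) {
  gq <- pracma::gaussLegendre(n_sub, b1, b2)
  w <- gq$w * gq$x; w <- w / sum(w)
  out <- numeric(length(r))
  for (j in seq_along(gq$x)) {
    out <- out + w[j] * (ring_pot_si(r, z, gq$x[j], ms$rho) +
                           layer_image_ring(r, z, gq$x[j], ms))
  }
  out
}

annulus_self_resistance <- function(b1, b2, ms) {
  # staggered node sets avoid the log-singular diagonal of the ring-ring kernel
  g1 <- pracma::gaussLegendre(64, b1, b2)
  g2 <- pracma::gaussLegendre(65, b1, b2)
  w1 <- g1$w * g1$x; w1 <- w1 / sum(w1)
  w2 <- g2$w * g2$x; w2 <- w2 / sum(w2)
  tot <- 0
  for (i in seq_along(g1$x)) {
    v <- ring_pot_si(g2$x, 0, g1$x[i], ms$rho) +
      layer_image_ring(g2$x, 0, g1$x[i], ms)
    tot <- tot + w1[i] * sum(w2 * v)
  }
  tot
}

#' Cross-resistance matrix of an array
#'
#' Entry (i, j) is the disk-averaged potential rise at active electrode i,
#' referenced to the return surface, per ampere injected from active electrode
#' j under the UCD boundary condition, with the counter-current collected by
#' the peripheral return ring (modelled as a uniformly distributed annular
#' sink). Referencing to the return makes the matrix a two-terminal resistance
#' matrix: symmetric by reciprocity, positive definite, with diagonal entries
#' close to the UCD access resistance of a single electrode. The raw
#' electrode-electrode kernel couplings and the ring terms are kept alongside
#' for field superposition.
#'
#' @param layout A `pv_layout`.
#' @param medium A `pv_medium`.
#' @return A `pv_rmatrix`: list with `R` (n x n, ohms, return-ring sink
#'   included), `ring_mutual` (potential at each pixel per ampere of ring
#'   current, ohms), `ring_self` (ring access resistance, ohms), `layout`,
#'   `medium`.
#' @examples
#' lay <- build_hex_array(40, 300)
#' rm <- cross_resistance_matrix(lay, medium())
#' rm$R[1, 2] / 1e3   # nearest-neighbour coupling, kOhm
#' @export
cross_resistance_matrix <- function(layout, medium) {
  stopifnot(inherits(layout, "pv_layout"), inherits(medium, "pv_medium"))
  n <- n_pixels(layout)
  if (n < 1) stop("layout has no pixels")
  ms <- medium_si(medium)
  a <- layout$electrode_radius * 1e-6
  cen <- layout$centers * 1e-6
  D <- as.matrix(dist(cen))
  if (n > 1 && min(D[upper.tri(D)]) < 2 * a)
    stop("invalid geometry: electrodes overlap")

  # homogeneous mutual-resistance profile, disk-averaged, splined over distance
  if (n > 1) {
    dmax <- max(D)
    dg <- unique(c(seq(2 * a, min(10 * a, dmax), length.out = 8),
                   seq(min(12 * a, dmax), dmax * 1.0001, length.out = 60)))
    mh <- vapply(dg, ucd_mutual_hom, numeric(1), a = a, rho = ms$rho)
    mi <- layer_image_point(dg, 0, ms)
    sp <- splinefun(dg, mh + mi, method = "natural")
    K <- matrix(sp(D), n)
  } else {
    K <- matrix(0, 1, 1)
  }
  diag(K) <- 8 * ms$rho / (3 * pi^2 * a) + layer_image_point(0, 0, ms)

  b1 <- layout$return_inner * 1e-6
  b2 <- layout$return_outer * 1e-6
  rad <- sqrt(rowSums(cen^2))
  rv <- annulus_pot(rad, 0, b1, b2, ms)
  rs <- annulus_self_resistance(b1, b2, ms)

  # injection at j raises phi at i by K_ij and pulls the whole bath down
  # through the ring sink; referencing to the ring surface gives the
  # reciprocal two-terminal matrix
  R <- K - matrix(rv, n, n) - matrix(rv, n, n, byrow = TRUE) + rs
  structure(list(R = R, kernel_matrix = K, ring_mutual = rv, ring_self = rs,
                 distances = D, layout = layout, medium = medium),
            class = "pv_rmatrix")
}

#' @export
print.pv_rmatrix <- function(x, ...) {
  n <- nrow(x$R)
  nn <- if (n > 1) {
    d <- x$distances; diag(d) <- Inf
    mean(x$R[abs(d - min(d)) < 1e-12]) / 1e3
  } else NA
  cat(sprintf("<pv_rmatrix> %d electrodes; diagonal %.3g kOhm; nearest-neighbour %.3g kOhm\n",
              n, mean(diag(x$R)) / 1e3, nn))
  invisible(x)
}

# coupling matrix seen by the circuit: identical to R (active electrode vs
# return surface, per ampere, ring carrying the counter-current)
circuit_coupling <- function(rmat) rmat$R
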
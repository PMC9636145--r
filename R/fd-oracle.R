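# Finite-difference (finite-volume) solution of the volume-conduction Poisson
# problem on a tensor-product grid over the half-space z >= 0. Used as an
# independent numerical oracle for the semi-analytic disk/ring kernels, not in
# the production path.

#' Stretched tensor grid for the FD oracle
#'
#' Builds node coordinate vectors that are uniform (spacing `h_fine`) inside
#' the refinement box and geometrically stretched outward to `extent`, so the
#' far Dirichlet boundary can sit many array diameters away at modest node
#' counts.
#'
#' @param fine_half Half-width of the finely resolved region in x and y, um.
#' @param fine_depth Depth of the finely resolved region in z, um.
#' @param h_fine Fine spacing, um.
#' @param extent Distance from the origin to the outer boundary, um.
#' @param growth Geometric growth factor of the stretched spacings.
#' @return List with node vectors `x`, `y`, `z` (um).
#' @export
fd_grid <- function(fine_half, fine_depth, h_fine, extent, growth = 1.3) {
  stretch <- function(from, to) {
    out <- numeric(0)
    h <- h_fine
    p <- from
    while (p < to) {
      h <- h * growth
      p <- min(p + h, to)
      out <- c(out, p)
    }
    out
  }
  x1 <- seq(-fine_half, fine_half, by = h_fine)
  xr <- stretch(fine_half, extent)
  x <- c(-rev(xr), x1, xr)
  z1 <- seq(0, fine_depth, by = h_fine)
  z <- c(z1, stretch(fine_depth, extent))
  list(x = x, y = x, z = z)
}

#' Finite-difference Poisson oracle for disk sources on the insulating plane
#'
#' Solves `div(sigma grad phi) = 0` over the box spanned by `grid`, with a
#' zero-flux (Neumann) condition on the z = 0 plane except over the source
#' disks, and the potential prescribed on the five outer faces (zero by
#' default, or values supplied by `dirichlet`). Disks are either UCD (a fixed
#' uniform current density, scaled so the discretized disk injects exactly the
#' requested current) or EP (an equipotential patch; its potential is scaled
#' after the solve so the patch passes the requested current).
#'
#' Second-order finite-volume discretization; symmetric positive definite
#' system solved by sparse Cholesky.
#'
#' @param grid List with ascending node vectors `x`, `y`, `z` (um), `z[1] = 0`.
#' @param sources Data frame with columns `x`, `y` (disk centres, um),
#'   `radius` (um), `current` (A), and optionally `mode` ("UCD" or "EP").
#' @param medium A `pv_medium` (homogeneous; the layer, if any, is ignored by
#'   the oracle and a warning is raised).
#' @param dirichlet Optional function `f(x, y, z)` (um) returning boundary
#'   potentials in volts on the outer faces.
#' @return A `pv_fdsolution`: list with `grid`, `phi` (3-D array, volts),
#'   and `lookup(x, y, z)` trilinear interpolation helper.
#' @export
fd_poisson_oracle <- function(grid, sources, medium, dirichlet = NULL) {
  stopifnot(is.list(grid), all(c("x", "y", "z") %in% names(grid)))
  if (!is.null(medium$layer_thickness))
    warning("FD oracle ignores the layered medium; using the retinal resistivity only")
  if (abs(grid$z[1]) > 1e-9) stop("grid$z must start at 0 (the electrode plane)")
  if (is.null(sources$mode)) sources$mode <- "UCD"
  # grid must resolve every electrode radius with >= 6 nodes across
  hx <- min(diff(grid$x))
  if (any(2 * sources$radius / hx < 6))
    stop("grid too coarse: electrode diameter must span at least 6 nodes")

  ms <- medium_si(medium)
  sigma <- 1 / ms$rho
  x <- grid$x * 1e-6; y <- grid$y * 1e-6; z <- grid$z * 1e-6
  nx <- length(x); ny <- length(y); nz <- length(z)
  idx <- function(i, j, k) (k - 1L) * nx * ny + (j - 1L) * nx + i

  # control-volume half-widths
  cw <- function(v) {
    n <- length(v)
    d <- diff(v)
    w <- c(d[1] / 2, (d[-1] + d[-(n - 1)]) / 2, d[n - 1] / 2)
    w
  }
  wx <- cw(x); wy <- cw(y); wz <- cw(z)
  # on the z = 0 face the control volume extends only upward
  # (cw already handles this since z starts at 0)

  rhs <- numeric(nx * ny * nz)

  interior <- array(TRUE, c(nx, ny, nz))
  interior[c(1, nx), , ] <- FALSE
  interior[, c(1, ny), ] <- FALSE
  interior[, , nz] <- FALSE          # top face Dirichlet; z = 0 stays interior

  bvals <- array(0, c(nx, ny, nz))
  if (!is.null(dirichlet)) {
    for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
      if (!interior[i, j, k])
        bvals[i, j, k] <- dirichlet(grid$x[i], grid$y[j], grid$z[k])
    }
  }

  # EP patches: collapse their nodes onto one unknown each handled by
  # constraining them to a fixed potential of 1 V, then rescaling currents.
  ep_id <- array(0L, c(nx, ny, nz))
  n_ep <- 0L
  src_flux <- array(0, c(nx, ny))    # UCD current density (A/m^2) on z=0 cells
  for (s in seq_len(nrow(sources))) {
    cx <- sources$x[s] * 1e-6; cy <- sources$y[s] * 1e-6
    ra <- sources$radius[s] * 1e-6
    on_disk <- outer(x - cx, y - cy, function(a, b) sqrt(a^2 + b^2)) <= ra
    if (!any(on_disk)) stop("source disk ", s, " not resolved by the grid")
    if (sources$mode[s] == "UCD") {
      area <- sum(outer(wx, wy)[on_disk])
      src_flux[on_disk] <- src_flux[on_disk] + sources$current[s] / area
    } else {
      n_ep <- n_ep + 1L
      ep_id[, , 1][on_disk] <- n_ep
    }
  }

  # assemble fluxes between neighbouring control volumes (vectorized)
  ntot <- nx * ny * nz
  faces <- function(dim) {
    if (dim == 1L) {
      i_ <- rep(seq_len(nx - 1), times = ny * nz)
      j_ <- rep(rep(seq_len(ny), each = nx - 1), times = nz)
      k_ <- rep(seq_len(nz), each = (nx - 1) * ny)
      list(a = idx(i_, j_, k_), b = idx(i_ + 1L, j_, k_),
           g = sigma * wy[j_] * wz[k_] / (x[i_ + 1] - x[i_]))
    } else if (dim == 2L) {
      i_ <- rep(seq_len(nx), times = (ny - 1) * nz)
      j_ <- rep(rep(seq_len(ny - 1), each = nx), times = nz)
      k_ <- rep(seq_len(nz), each = nx * (ny - 1))
      list(a = idx(i_, j_, k_), b = idx(i_, j_ + 1L, k_),
           g = sigma * wx[i_] * wz[k_] / (y[j_ + 1] - y[j_]))
    } else {
      i_ <- rep(seq_len(nx), times = ny * (nz - 1))
      j_ <- rep(rep(seq_len(ny), each = nx), times = nz - 1)
      k_ <- rep(seq_len(nz - 1), each = nx * ny)
      list(a = idx(i_, j_, k_), b = idx(i_, j_, k_ + 1L),
           g = sigma * wx[i_] * wy[j_] / (z[k_ + 1] - z[k_]))
    }
  }
  fx <- faces(1L); fy <- faces(2L); fz <- faces(3L)
  fa <- c(fx$a, fy$a, fz$a); fb <- c(fx$b, fy$b, fz$b); fg <- c(fx$g, fy$g, fz$g)
  A <- Matrix::sparseMatrix(
    i = c(fa, fb, fa, fb), j = c(fb, fa, fa, fb),
    x = c(-fg, -fg, fg, fg), dims = c(ntot, ntot))

  # Neumann source injection on z = 0
  inj <- src_flux * outer(wx, wy)
  nz0 <- which(inj != 0, arr.ind = TRUE)
  if (nrow(nz0)) rhs[idx(nz0[, 1], nz0[, 2], 1L)] <- inj[nz0]

  free <- as.vector(interior) & as.vector(ep_id == 0L)
  fixed_vals <- as.vector(bvals)
  fixed_vals[as.vector(ep_id != 0L)] <- 1   # EP patches at 1 V before rescaling
  fixed <- !free

  rhs_free <- rhs[free] - as.vector(A[free, fixed, drop = FALSE] %*% fixed_vals[fixed])
  Aff <- Matrix::forceSymmetric(A[free, free])
  sol <- tryCatch({
    ch <- Matrix::Cholesky(Aff, LDL = FALSE, super = TRUE)
    as.vector(Matrix::solve(ch, rhs_free))
  }, error = function(e) stop("FD solver failed: ", conditionMessage(e)))
  phi <- fixed_vals
  phi[free] <- sol
  res <- as.vector(A %*% phi) - rhs
  resn <- max(abs(res[free]))
  if (!is.finite(resn)) stop("FD solver produced a non-finite residual")

  # rescale EP patches so each passes its requested current
  if (n_ep > 0L) {
    for (e in seq_len(n_ep)) {
      nodes <- which(as.vector(ep_id == e))
      Ie <- sum(as.vector(A[nodes, , drop = FALSE] %*% phi) - rhs[nodes])
      want <- sources$current[sources$mode == "EP"][e]
      phi <- phi * want / Ie   # valid for a single EP patch with zero far field
    }
  }

  phi <- array(phi, c(nx, ny, nz))
  lookup <- function(px, py, pz) {
    fi <- approx(grid$x, seq_len(nx), px, rule = 2)$y
    fj <- approx(grid$y, seq_len(ny), py, rule = 2)$y
    fk <- approx(grid$z, seq_len(nz), pz, rule = 2)$y
    tri <- function(f) list(lo = pmax(floor(f), 1), w = f - floor(f))
    a <- tri(fi); b <- tri(fj); c3 <- tri(fk)
    out <- numeric(length(px))
    for (q in seq_along(px)) {
      i0 <- min(a$lo[q], nx - 1); j0 <- min(b$lo[q], ny - 1); k0 <- min(c3$lo[q], nz - 1)
      wi <- a$w[q]; wj <- b$w[q]; wk <- c3$w[q]
      out[q] <-
        phi[i0, j0, k0] * (1 - wi) * (1 - wj) * (1 - wk) +
        phi[i0 + 1, j0, k0] * wi * (1 - wj) * (1 - wk) +
        phi[i0, j0 + 1, k0] * (1 - wi) * wj * (1 - wk) +
        phi[i0 + 1, j0 + 1, k0] * wi * wj * (1 - wk) +
        phi[i0, j0, k0 + 1] * (1 - wi) * (1 - wj) * wk +
        phi[i0 + 1, j0, k0 + 1] * wi * (1 - wj) * wk +
        phi[i0, j0 + 1, k0 + 1] * (1 - wi) * wj * wk +
        phi[i0 + 1, j0 + 1, k0 + 1] * wi * wj * wk
    }
    out
  }
  structure(list(grid = grid, phi = phi, residual = resn, lookup = lookup),
            class = "pv_fdsolution")
}
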
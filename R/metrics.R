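# Field superposition metrics: everything here is linear in the pixel currents,
# with the return ring automatically carrying the counter-current.

# radial kernel caches at a given height (SI internally, um/V at the surface)
step_kernels <- function(rmat, z_um) {
  ms <- medium_si(rmat$medium)
  a <- rmat$layout$electrode_radius * 1e-6
  dmax <- (rmat$layout$array_diameter * 1.6 + 100) * 1e-6
  lapply(z_um, function(zu) ucd_kernel_spline(a, zu * 1e-6, ms, dmax))
}

# potential (V) at arbitrary points for a current vector; pts in um (n x 2),
# z scalar um
superpose_at <- function(points_um, z_um, currents, rmat, kern = NULL) {
  if (is.null(kern)) kern <- step_kernels(rmat, z_um)[[1]]
  cen <- rmat$layout$centers
  Dp <- sqrt(outer(points_um[, 1], cen[, 1], "-")^2 +
             outer(points_um[, 2], cen[, 2], "-")^2) * 1e-6
  ms <- medium_si(rmat$medium)
  base <- drop(matrix(kern(Dp), nrow(points_um)) %*% currents)
  r_obs <- sqrt(points_um[, 1]^2 + points_um[, 2]^2) * 1e-6
  iring <- -sum(currents)
  ringv <- annulus_pot(r_obs, z_um * 1e-6,
                       rmat$layout$return_inner * 1e-6,
                       rmat$layout$return_outer * 1e-6, ms)
  base + iring * ringv
}

#' Electric potential map in the medium
#'
#' Superposes the elementary fields of all pixels, weighted by their currents,
#' on a horizontal plane at height `z`. Linear in the current vector; the
#' return ring sinks the net current.
#'
#' @param currents Per-pixel currents, A.
#' @param rmat A `pv_rmatrix` (carries layout and medium).
#' @param z Height above the electrode plane, um (must be >= 0).
#' @param x,y Grid coordinate vectors, um (defaults span the device).
#' @return A `pv_fieldmap`: list with `x`, `y`, `z`, `potential` (matrix,
#'   volts).
#' @export
potential_map <- function(currents, rmat, z, x = NULL, y = NULL) {
  if (z < 0) stop("out of domain: z must be >= 0 (above the electrode plane)")
  n <- n_pixels(rmat$layout)
  if (length(currents) != n) stop("currents length must match the pixel count")
  R2 <- rmat$layout$array_diameter / 2 * 1.1
  if (is.null(x)) x <- seq(-R2, R2, length.out = 101)
  if (is.null(y)) y <- seq(-R2, R2, length.out = 101)
  pts <- cbind(rep(x, times = length(y)), rep(y, each = length(x)))
  v <- superpose_at(pts, z, currents, rmat)
  structure(list(x = x, y = y, z = z,
                 potential = matrix(v, length(x), length(y))),
            class = "pv_fieldmap")
}

#' Trans-cellular potential step
#'
#' The stimulation-strength proxy for bipolar cells: the potential difference
#' between a plane just above the implant (the dendritic end, default 10 um)
#' and the plane of the axonal terminals in the mid inner plexiform layer
#' (default 57 um), evaluated at the pixel centres and optionally along row
#' rasters.
#'
#' @inheritParams potential_map
#' @param z_low,z_high Heights of the two planes, um (`z_low < z_high`).
#' @param at `"centers"` for pixel centres only, or `"raster"` to add
#'   row-raster means (4 um sampling along each interior row).
#' @return List with `step` (V at pixel centres), `z_low`, `z_high`, and, for
#'   `at = "raster"`, `row_index` and `row_means`.
#' @export
transcellular_step <- function(currents, rmat, z_low = 10, z_high = 57,
                               at = c("centers", "raster")) {
  at <- match.arg(at)
  if (z_low >= z_high) stop("z_low must be below z_high")
  if (z_low < 0) stop("out of domain: z_low must be >= 0")
  kerns <- step_kernels(rmat, c(z_low, z_high))
  cen <- rmat$layout$centers
  st <- superpose_at(cen, z_low, currents, rmat, kerns[[1]]) -
        superpose_at(cen, z_high, currents, rmat, kerns[[2]])
  out <- list(step = st, z_low = z_low, z_high = z_high)
  if (at == "raster") {
    lay <- rmat$layout
    rlim <- lay$array_diameter / 2 - 2 * lay$row_pitch
    rows <- sort(unique(lay$row_index[abs(lay$row_index * lay$row_pitch) < rlim]))
    rm_ <- vapply(rows, function(k) {
      yy <- k * lay$row_pitch
      xmax <- sqrt(max(rlim^2 - yy^2, 0))
      xs <- seq(-xmax, xmax, by = 4)
      pts <- cbind(xs, yy)
      mean(superpose_at(pts, z_low, currents, rmat, kerns[[1]]) -
           superpose_at(pts, z_high, currents, rmat, kerns[[2]]))
    }, numeric(1))
    out$row_index <- rows
    out$row_means <- rm_
  }
  out
}

#' Grating contrast of a stimulation map
#'
#' Compares the mean trans-cellular step above bright versus dark grating rows,
#' over interior pixels (at least two row pitches inside the rim). Two figures
#' are reported: the Michelson contrast `100 (Vb - Vd) / (Vb + Vd)` — the
#' standard grating-contrast measure, equal to 100 exactly when the dark-row
#' step reaches zero and larger when dark rows are driven negative — and the
#' bright-relative modulation `100 (Vb - Vd) / Vb`.
#'
#' @param step Result of [transcellular_step()] (or a numeric vector of
#'   per-pixel steps, V).
#' @param pattern The row-grating `pv_pattern` that was projected.
#' @param layout The `pv_layout`.
#' @return A `pv_contrast`: list with `bright_mean_mV`, `dark_mean_mV`,
#'   `contrast` (Michelson, percent), `modulation` (percent), `n_bright`,
#'   `n_dark`, `row_means` when available.
#' @export
grating_contrast <- function(step, pattern, layout) {
  stopifnot(inherits(layout, "pv_layout"))
  stv <- if (is.list(step)) step$step else step
  bright <- pattern_weights(pattern, layout, frame = 1L) > 0.5
  interior <- interior_pixels(layout, 2)
  if (!any(interior & !bright))
    stop("insufficient geometry: no interior dark rows")
  vb <- mean(stv[interior & bright])
  vd <- mean(stv[interior & !bright])
  res <- list(bright_mean_mV = vb * 1e3, dark_mean_mV = vd * 1e3,
              contrast = 100 * (vb - vd) / (vb + vd),
              modulation = 100 * (vb - vd) / vb,
              n_bright = sum(interior & bright), n_dark = sum(interior & !bright))
  if (is.list(step) && !is.null(step$row_means)) {
    br <- pattern_weights(pattern, layout, frame = 1L)
    # classify rows via any pixel in the row
    rowb <- vapply(step$row_index, function(k)
      mean(br[layout$row_index == k]) > 0.5, logical(1))
    vbr <- mean(step$row_means[rowb]); vdr <- mean(step$row_means[!rowb])
    res$row_bright_mean_mV <- vbr * 1e3
    res$row_dark_mean_mV <- vdr * 1e3
    res$row_contrast <- 100 * (vbr - vdr) / (vbr + vdr)
  }
  structure(res, class = "pv_contrast")
}

#' @export
print.pv_contrast <- function(x, ...) {
  cat(sprintf("<pv_contrast> bright %.2f mV, dark %.2f mV -> contrast %.1f%% (modulation %.1f%%)\n",
              x$bright_mean_mV, x$dark_mean_mV, x$contrast, x$modulation))
  invisible(x)
}

# ---- far-field proxy --------------------------------------------------------

#' Far-field observer coefficients
#'
#' Potential per ampere of each pixel (return-ring sink included) at a distant
#' observer point, default on-axis 5 mm above the array. These replace an
#' anatomical eye/head conduction model: only the waveform shape and its
#' normalized frequency dependence are meaningful, never absolute amplitudes.
#'
#' @param rmat A `pv_rmatrix`.
#' @param observer Observer position `(x, y, z)`, um.
#' @return Numeric vector, V/A per pixel.
#' @export
far_field_coeffs <- function(rmat, observer = c(0, 0, 5000)) {
  ms <- medium_si(rmat$medium)
  cen <- rmat$layout$centers
  dx <- (observer[1] - cen[, 1]) * 1e-6
  dy <- (observer[2] - cen[, 2]) * 1e-6
  z <- observer[3] * 1e-6
  r <- sqrt(dx^2 + dy^2)
  # pixels are effectively point sources at 5 mm
  src <- ms$rho / (2 * pi * sqrt(r^2 + z^2)) + layer_image_point(r, z, ms)
  robs <- sqrt(sum(observer[1:2]^2)) * 1e-6
  ringv <- annulus_pot(robs, z, rmat$layout$return_inner * 1e-6,
                       rmat$layout$return_outer * 1e-6, ms)
  src - ringv
}

#' Far-field waveform of a simulation trace
#'
#' Scalar observer signal `c . I(t)`: the linear far-field proxy for signals
#' recorded at a distance from the implant (e.g. at the cornea).
#'
#' @param trace A `pv_trace`.
#' @param coeffs Observer coefficients from [far_field_coeffs()] (computed at
#'   the default observer if missing).
#' @return Data frame with `t_ms` and `v` (volts).
#' @export
far_field_waveform <- function(trace, coeffs = NULL) {
  if (is.null(coeffs)) coeffs <- far_field_coeffs(trace$rmat)
  data.frame(t_ms = trace$t, v = drop(trace$I %*% coeffs))
}

#' Peak-to-peak amplitude in a time window
#'
#' @param x Data frame with `t_ms` and `v` (as from [far_field_waveform()]),
#'   or a numeric vector.
#' @param window Optional `c(t0, t1)` in ms.
#' @return `max - min` over the window.
#' @export
peak_to_peak <- function(x, window = NULL) {
  if (is.data.frame(x)) {
    v <- x$v
    if (!is.null(window)) v <- v[x$t_ms >= window[1] & x$t_ms <= window[2]]
  } else v <- x
  if (!length(v)) stop("empty window")
  max(v) - min(v)
}

#' Normalized far-field amplitude versus repetition rate
#'
#' Runs the full-field drive to periodic steady state at each repetition rate,
#' measures the peak-to-peak far-field amplitude over one period, and
#' normalizes by the value at the lowest rate (conventionally 1 Hz). As the
#' rate grows, interfaces stay charged between pulses, the diodes are held
#' closer to conduction, and the injected current — hence the far-field
#' amplitude — shrinks.
#'
#' @param rates Repetition rates, Hz (the first is the normalization point).
#' @param layout,rmat,params Array description.
#' @param peak_irradiance Irradiance, mW/mm^2.
#' @param pulse_width Pulse width, ms.
#' @param ... Passed to [run_to_steady_state()].
#' @return Data frame with `rate_Hz`, `p2p_V`, `normalized`.
#' @export
frequency_sweep <- function(rates, layout, rmat, params, peak_irradiance = 1.2,
                            pulse_width = 4, ...) {
  if (!length(rates)) stop("empty rate list")
  cf <- far_field_coeffs(rmat)
  p2p <- vapply(rates, function(rt) {
    drv <- project_pattern(layout, pattern_full_field(), peak_irradiance,
                           pulse_width, rt, duration = 1000 / rt)
    tr <- run_to_steady_state(drv, rmat, params, ...)
    peak_to_peak(far_field_waveform(tr, cf))
  }, numeric(1))
  data.frame(rate_Hz = rates, p2p_V = p2p, normalized = p2p / p2p[1])
}
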
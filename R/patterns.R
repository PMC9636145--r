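#' Spatial illumination patterns
#'
#' Patterns assign a relative irradiance weight in `[0, 1]` to each pixel of a
#' layout. `pattern_grating()` describes a square-wave bar grating whose bars
#' run parallel to the lattice rows by default; with `bar_width` equal to the
#' row pitch and zero phase it illuminates alternating pixel rows exactly, the
#' configuration used for grating-acuity work. `pattern_field_stop()` is a
#' regular octagon (flat sides facing the axes) emulating a projection-system
#' field stop; `pattern_full_field()` illuminates everything;
#' `pattern_mask()` takes explicit per-pixel weights.
#'
#' @param bar_width Grating bar width (half period), um.
#' @param phase Lateral shift of the grating perpendicular to the bars, um.
#' @param orientation Bar direction in degrees; 0 keeps bars along lattice rows.
#' @param stop_width Octagon width across flats, um.
#' @param mask Numeric vector of per-pixel weights in `[0, 1]`.
#' @return A `pv_pattern` object.
#' @examples
#' lay <- build_hex_array(40, 400)
#' g <- pattern_grating(bar_width = lay$row_pitch)
#' w <- pattern_weights(g, lay)          # alternating rows
#' @export
pattern_grating <- function(bar_width, phase = 0, orientation = 0) {
  stopifnot(bar_width > 0)
  structure(list(kind = "grating", bar_width = bar_width, phase = phase,
                 orientation = orientation), class = "pv_pattern")
}

#' @rdname pattern_grating
#' @export
pattern_full_field <- function() {
  structure(list(kind = "full_field"), class = "pv_pattern")
}

#' @rdname pattern_grating
#' @export
pattern_field_stop <- function(stop_width) {
  stopifnot(stop_width > 0)
  structure(list(kind = "field_stop_octagon", stop_width = stop_width),
            class = "pv_pattern")
}

#' @rdname pattern_grating
#' @export
pattern_mask <- function(mask) {
  if (any(mask < 0 | mask > 1)) stop("mask weights must lie in [0, 1]")
  structure(list(kind = "custom_mask", mask = mask), class = "pv_pattern")
}

#' @export
print.pv_pattern <- function(x, ...) {
  cat("<pv_pattern>", x$kind,
      switch(x$kind,
             grating = sprintf("bar %g um, phase %g um, %g deg",
                               x$bar_width, x$phase, x$orientation),
             field_stop_octagon = sprintf("width %g um", x$stop_width),
             ""), "\n")
  invisible(x)
}

#' Evaluate a pattern on a layout
#'
#' @param pattern A `pv_pattern`.
#' @param layout A `pv_layout`.
#' @param frame Frame number (1 or 2). For gratings, frame 2 is the
#'   contrast-reversed pattern (bright and dark bars swapped); other patterns
#'   are frame-independent.
#' @return Numeric vector of per-pixel weights in `[0, 1]`.
#' @export
pattern_weights <- function(pattern, layout, frame = 1L) {
  stopifnot(inherits(pattern, "pv_pattern"), inherits(layout, "pv_layout"))
  xy <- layout$centers
  switch(pattern$kind,
    full_field = rep(1, nrow(xy)),
    custom_mask = {
      if (length(pattern$mask) != nrow(xy))
        stop("mask length does not match the number of pixels")
      pattern$mask
    },
    grating = {
      th <- pattern$orientation * pi / 180
      # coordinate perpendicular to the bars
      s <- -xy[, 1] * sin(th) + xy[, 2] * cos(th)
      ph <- pattern$phase + if (frame %% 2 == 0) pattern$bar_width else 0
      # rows sit mid-bar at zero phase
      idx <- floor((s + pattern$bar_width / 2 + ph) / pattern$bar_width)
      as.numeric(idx %% 2 == 0)
    },
    field_stop_octagon = {
      w2 <- pattern$stop_width / 2
      x <- abs(xy[, 1]); y <- abs(xy[, 2])
      as.numeric(x <= w2 & y <= w2 & (x + y) <= w2 * sqrt(2))
    },
    stop("unknown pattern kind: ", pattern$kind)
  )
}

#' Project an optical pattern onto an array as a pulsed drive
#'
#' Combines a spatial pattern, a peak irradiance and pulse-train timing into a
#' per-pixel irradiance waveform. Irradiance is rectangular within each pulse.
#' For alternating patterns (gratings), the complementary frame is shown after
#' every `reversal_period`; pulses and reversals are aligned so a reversal
#' never splits a pulse when `reversal_period` is a multiple of the pulse
#' period.
#'
#' @param layout A `pv_layout`.
#' @param pattern A `pv_pattern`.
#' @param peak_irradiance Peak irradiance on bright pixels, mW/mm^2.
#' @param pulse_width Pulse duration, ms.
#' @param rate Pulse repetition rate, Hz.
#' @param reversal_period Pattern reversal period, ms (`Inf` = static pattern).
#' @param duration Total drive duration, ms.
#' @return A `pv_drive` object.
#' @examples
#' lay <- build_hex_array(40, 400)
#' drv <- project_pattern(lay, pattern_full_field(), 8, pulse_width = 10,
#'                        rate = 40, duration = 100)
#' @export
project_pattern <- function(layout, pattern, peak_irradiance, pulse_width,
                            rate, reversal_period = Inf, duration = NULL) {
  stopifnot(peak_irradiance >= 0, pulse_width > 0, rate > 0)
  period <- 1000 / rate
  if (pulse_width >= period)
    stop("invalid timing: pulse_width (", pulse_width,
         " ms) must be shorter than the pulse period (", round(period, 3), " ms)")
  if (is.null(duration)) duration <- if (is.finite(reversal_period)) 2 * reversal_period else period
  m1 <- pattern_weights(pattern, layout, frame = 1L)
  m2 <- pattern_weights(pattern, layout, frame = 2L)
  structure(list(layout = layout, pattern = pattern,
                 peak_irradiance = peak_irradiance,
                 mask1 = m1, mask2 = m2,
                 pulse_width = pulse_width, rate = rate,
                 reversal_period = reversal_period, duration = duration),
            class = "pv_drive")
}

#' @export
print.pv_drive <- function(x, ...) {
  cat(sprintf("<pv_drive> %s, %g mW/mm^2 peak, %g ms pulses @ %g Hz, %s, %g ms\n",
              x$pattern$kind, x$peak_irradiance, x$pulse_width, x$rate,
              if (is.finite(x$reversal_period))
                sprintf("reversal every %g ms", x$reversal_period) else "static",
              x$duration))
  invisible(x)
}

#' Per-pixel irradiance of a drive at given times
#'
#' @param drive A `pv_drive`.
#' @param t Time or vector of times, ms.
#' @return For scalar `t`, a vector of per-pixel irradiances (mW/mm^2); for
#'   vector `t`, a `length(t)` x n-pixel matrix.
#' @export
drive_irradiance <- function(drive, t) {
  period <- 1000 / drive$rate
  tm <- t %% period
  in_pulse <- tm < drive$pulse_width - 1e-12 | abs(tm) < 1e-12
  frame2 <- if (is.finite(drive$reversal_period))
    (floor(t / drive$reversal_period) %% 2) == 1 else rep(FALSE, length(t))
  out <- matrix(0, length(t), length(drive$mask1))
  for (i in which(in_pulse)) {
    m <- if (frame2[i]) drive$mask2 else drive$mask1
    out[i, ] <- drive$peak_irradiance * m
  }
  if (length(t) == 1L) drop(out) else out
}

# times (ms) of pulse onsets within [0, duration)
pulse_onsets <- function(drive) {
  period <- 1000 / drive$rate
  seq(0, drive$duration - 1e-9, by = period)
}
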
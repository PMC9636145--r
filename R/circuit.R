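#' Photodiode, photosensitivity and interface parameters
#'
#' Each pixel is a photocurrent source in parallel with a single Si photodiode,
#' feeding the electrolyte through the capacitive electrode-electrolyte
#' interface of its active electrode; all pixels share the common return and
#' its (much larger) interface capacitance. Sign conventions: anodic current
#' out of the active electrode is positive; diode forward bias is
#' active-terminal positive.
#'
#' Diode defaults are calibrated so that the turn-on voltage is about 0.5 V at
#' stimulation-scale current (~0.5 uA) and the open-circuit photovoltage stays
#' at or below 0.6 V under strong (8 mW/mm^2) illumination.
#'
#' @param I0 Diode saturation current, A.
#' @param n Diode ideality factor.
#' @param VT Thermal voltage, V.
#' @param shunt Optional shunt conductance across the diode, S (default 0).
#' @return `diode_params()` returns a `pv_diode` list.
#' @export
diode_params <- function(I0 = 1.2e-12, n = 1.5, VT = 25.85e-3, shunt = 0) {
  stopifnot(I0 > 0, n >= 1, VT > 0, shunt >= 0)
  structure(list(I0 = I0, n = n, VT = VT, shunt = shunt), class = "pv_diode")
}

#' @rdname diode_params
#' @param responsivity Photodiode responsivity, A/W.
#' @param area_ratio Photosensitive area as a multiple of the active-electrode
#'   area (the photosensitive area per pixel is about twice the electrode).
#' @export
photo_params <- function(responsivity = 0.51, area_ratio = 2) {
  stopifnot(responsivity > 0, area_ratio > 0)
  structure(list(responsivity = responsivity, area_ratio = area_ratio),
            class = "pv_photo")
}

#' @rdname diode_params
#' @param specific_capacitance Interface specific capacitance of the
#'   sputtered-iridium-oxide coating, mF/cm^2.
#' @param return_rc Time constant of the common return interface, ms; the
#'   return capacitance is chosen as `return_rc / ring access resistance`.
#' @export
interface_params <- function(specific_capacitance = 6, return_rc = 40) {
  stopifnot(specific_capacitance > 0, return_rc > 0)
  structure(list(specific_capacitance = specific_capacitance,
                 return_rc = return_rc), class = "pv_interface")
}

#' Bundle per-array circuit parameters
#'
#' Derives the per-pixel quantities the solver needs (photosensitive area,
#' interface capacitance, return capacitance) from a layout and the component
#' parameter sets.
#'
#' @param layout A `pv_layout`.
#' @param rmat Optional `pv_rmatrix` (needed for the return capacitance; if
#'   absent the return RC is anchored to a nominal 3 kOhm ring resistance).
#' @param diode,photo,interface Component parameter sets.
#' @return A `pv_params` list: the components plus `electrode_area_cm2`,
#'   `photo_area_cm2`, `C_active` (F per pixel), `C_return` (F),
#'   `R_return` (ohm).
#' @examples
#' lay <- build_hex_array(40, 300)
#' pp <- pixel_params(lay)
#' pp$C_active   # ~15 nF for an 18 um SIROF electrode
#' @export
pixel_params <- function(layout, rmat = NULL, diode = diode_params(),
                         photo = photo_params(), interface = interface_params()) {
  stopifnot(inherits(layout, "pv_layout"))
  a_cm <- layout$electrode_radius * 1e-4
  e_area <- pi * a_cm^2
  p_area <- photo$area_ratio * e_area
  C_a <- interface$specific_capacitance * 1e-3 * e_area
  R_ret <- if (!is.null(rmat)) rmat$ring_self else 3e3
  C_r <- interface$return_rc * 1e-3 / R_ret
  structure(list(diode = diode, photo = photo, interface = interface,
                 layout = layout,
                 electrode_area_cm2 = e_area, photo_area_cm2 = p_area,
                 C_active = C_a, C_return = C_r, R_return = R_ret),
            class = "pv_params")
}

#' @export
print.pv_params <- function(x, ...) {
  cat(sprintf("<pv_params> C_active %.3g nF, C_return %.3g uF, diode I0 %.3g A (n = %g)\n",
              x$C_active * 1e9, x$C_return * 1e6, x$diode$I0, x$diode$n))
  invisible(x)
}

#' Photocurrent of a pixel
#'
#' Linear in irradiance: responsivity times irradiance times photosensitive
#' area.
#'
#' @param irradiance Irradiance, mW/mm^2 (may be a vector).
#' @param params A `pv_params` (or anything with `photo_area_cm2` and
#'   `photo$responsivity`).
#' @return Photocurrent, A.
#' @examples
#' lay <- build_hex_array(40, 300)
#' photocurrent(1, pixel_params(lay))   # ~0.26 uA
#' @export
photocurrent <- function(irradiance, params) {
  if (any(irradiance < 0)) stop("irradiance must be nonnegative")
  # 1 mW/mm^2 = 0.1 W/cm^2
  params$photo$responsivity * irradiance * 0.1 * params$photo_area_cm2
}

# diode conduction, clamped above v_lin to a linear extension so Newton
# iterates cannot overflow the exponential
diode_g <- function(V, d, v_lin = 1.5) {
  s <- d$n * d$VT
  hi <- V > v_lin
  out <- d$I0 * expm1(pmin(V, v_lin) / s)
  if (any(hi)) out[hi] <- out[hi] + d$I0 * exp(v_lin / s) / s * (V[hi] - v_lin)
  out + d$shunt * V
}

diode_gprime <- function(V, d, v_lin = 1.5) {
  s <- d$n * d$VT
  d$I0 / s * exp(pmin(V, v_lin) / s) + d$shunt
}

#' Diode dark current
#'
#' Shockley law `I0 (exp(V / (n VT)) - 1)` (plus the optional shunt term),
#' strictly increasing in forward bias.
#'
#' @param V Diode voltage, V (vectorized).
#' @param diode A `pv_diode`.
#' @return Current, A.
#' @examples
#' diode_dark_current(0.5, diode_params())   # ~0.5 uA at the turn-on knee
#' @export
diode_dark_current <- function(V, diode = diode_params()) {
  diode$I0 * expm1(V / (diode$n * diode$VT)) + diode$shunt * V
}

#' Open-circuit photovoltage
#'
#' With the electrolyte path removed, the diode clamps the pixel voltage where
#' dark current balances photocurrent: `n VT log(1 + Iph / I0)`. With a single
#' Si diode per pixel this stays near or below 0.6 V at any realistic
#' irradiance, which bounds every electrode voltage in the system.
#'
#' @inheritParams photocurrent
#' @return Voltage, V.
#' @examples
#' lay <- build_hex_array(40, 300)
#' open_circuit_voltage(8, pixel_params(lay))   # about 0.56 V
#' @export
open_circuit_voltage <- function(irradiance, params) {
  iph <- photocurrent(irradiance, params)
  d <- params$diode
  if (d$shunt == 0) return(d$n * d$VT * log1p(iph / d$I0))
  vapply(iph, function(ip) {
    stats::uniroot(function(v) diode_dark_current(v, d) - ip,
                   c(0, 2), tol = 1e-12)$root
  }, numeric(1))
}

#' Electrode charge density and interface voltage step of a pulse
#'
#' The bookkeeping behind stimulation safety: charge injected per electrode
#' area for a rectangular pulse, and the corresponding interface voltage step
#' across the interface capacitance.
#'
#' @param irradiance Pulse irradiance, mW/mm^2.
#' @param pulse_width Pulse width, ms.
#' @param params A `pv_params`.
#' @return List with `current_A`, `charge_density_mC_cm2`, `voltage_step_V`.
#' @examples
#' lay <- build_hex_array(40, 300)
#' pulse_charge(1.2, 10, pixel_params(lay))  # ~1.2 mC/cm^2 and ~0.2 V
#' @export
pulse_charge <- function(irradiance, pulse_width, params) {
  iph <- photocurrent(irradiance, params)
  q <- iph * pulse_width * 1e-3 / params$electrode_area_cm2   # C/cm^2
  list(current_A = iph,
       charge_density_mC_cm2 = q * 1e3,
       voltage_step_V = q / (params$interface$specific_capacitance * 1e-3))
}

# ---- network solver ---------------------------------------------------------

#' Solve the instantaneous nonlinear network currents
#'
#' Given the interface voltages and per-pixel irradiances, finds the pixel
#' currents satisfying `I_i = Iph_i - Idark(VD_i)` with
#' `VD_i = u_i - u_return + (M I)_i`, where `M` is the electrode-to-return
#' coupling through the electrolyte (cross-resistances with the ring folded
#' in). Damped Newton iteration; the system is monotone, so the solution is
#' unique.
#'
#' @param u Interface voltages of the active electrodes, V (length n).
#' @param irradiance Per-pixel irradiance, mW/mm^2 (length n or scalar).
#' @param rmat A `pv_rmatrix`.
#' @param params A `pv_params`.
#' @param u_return Return interface voltage, V.
#' @param conducting Logical mask of pixels whose diode participates; pixels
#'   marked `FALSE` are treated as non-conductive (current pinned at 0), the
#'   idealization of dark pixels biased far below the diode turn-on.
#' @param coupling Optional extra coupling matrix added to `M` (used
#'   internally by the implicit integrator).
#' @param tol Residual tolerance, A.
#' @param max_iter Newton iteration cap.
#' @return List with `I` (A), `V_D` (V), `phi` (electrolyte potential at each
#'   electrode relative to the return surface, V), `residual`, `iterations`.
#' @export
solve_network_currents <- function(u, irradiance, rmat, params, u_return = 0,
                                   conducting = NULL, coupling = NULL,
                                   tol = 1e-13, max_iter = 100) {
  n <- nrow(rmat$R)
  if (length(u) != n) stop("length(u) does not match the number of pixels")
  irr <- rep_len(irradiance, n)
  iph <- photocurrent(irr, params)
  M <- circuit_coupling(rmat)
  if (!is.null(coupling)) M <- M + coupling
  if (is.null(conducting)) conducting <- rep(TRUE, n)
  act <- which(conducting)
  I <- numeric(n)
  I[!conducting] <- 0
  d <- params$diode

  if (length(act) == 0)
    return(list(I = I, V_D = u - u_return, phi = rep(0, n), residual = 0,
                iterations = 0L))

  Ma <- M[act, act, drop = FALSE]
  ua <- u[act]; ipha <- iph[act]
  Ia <- numeric(length(act))
  resid <- function(Iv) Iv - ipha + diode_g(ua - u_return + drop(Ma %*% Iv), d)
  Fv <- resid(Ia)
  it <- 0L
  while (max(abs(Fv)) > tol && it < max_iter) {
    it <- it + 1L
    VD <- ua - u_return + drop(Ma %*% Ia)
    G <- diode_gprime(VD, d)
    J <- diag(length(act)) + G * Ma
    dI <- -solve(J, Fv)
    step <- 1
    repeat {
      In <- Ia + step * dI
      Fn <- resid(In)
      if (max(abs(Fn)) < max(abs(Fv)) || step < 1e-6) break
      step <- step / 2
    }
    Ia <- In; Fv <- Fn
  }
  if (max(abs(Fv)) > max(tol, 1e-10 * max(abs(ipha), 1e-12)))
    stop(sprintf("network solve did not converge: residual %.3g A after %d iterations",
                 max(abs(Fv)), it))
  I[act] <- Ia
  phi <- drop(M %*% I)
  list(I = I, V_D = u - u_return + phi, phi = phi,
       residual = max(abs(Fv)), iterations = it)
}

# ---- time integration -------------------------------------------------------

#' Initial circuit state
#'
#' @param layout A `pv_layout`.
#' @param u Interface voltages, V (scalar recycled).
#' @param u_return Return interface voltage, V.
#' @return A `pv_state` list.
#' @export
initial_state <- function(layout, u = 0, u_return = 0) {
  structure(list(u = rep_len(u, n_pixels(layout)), u_return = u_return),
            class = "pv_state")
}

#' Precondition selected pixels
#'
#' Sets the interface voltage of the designated pixels to `bias`, leaving all
#' others untouched — the optically controlled pre-charging that turns dark
#' pixels into transient returns for the following frame.
#'
#' @param state A `pv_state`.
#' @param pixels Integer indices of the pixels to precondition.
#' @param bias Target interface voltage, V (within -1..1).
#' @return The modified `pv_state`.
#' @export
precondition <- function(state, pixels, bias) {
  stopifnot(inherits(state, "pv_state"))
  if (bias < -1 || bias > 1) stop("bias must be within [-1, 1] V")
  if (length(pixels) && (min(pixels) < 1 || max(pixels) > length(state$u)))
    stop("unknown pixel index")
  state$u[pixels] <- bias
  state
}

#' Simulate the coupled array dynamics under a drive
#'
#' Advances the interface voltages `du_i/dt = I_i / C_active` (and the return
#' state) with an adaptive implicit (backward-Euler) integrator; the nonlinear
#' network is re-solved at every stage. Pulse edges are exact step boundaries.
#' Local error is controlled by step doubling against `rtol_V`.
#'
#' @param drive A `pv_drive`.
#' @param rmat A `pv_rmatrix` for the same layout.
#' @param params A `pv_params`.
#' @param init A `pv_state` (default: everything discharged).
#' @param dt_out Output sampling interval, ms.
#' @param rtol_V Local error tolerance per step, V.
#' @param dt_max Maximum step, ms.
#' @param dt_fixed If given, disables adaptivity and uses this fixed step (ms)
#'   — the configuration used as a fine-step reference oracle.
#' @param conducting Optional logical mask passed to the network solver.
#' @return A `pv_trace`: list with `t` (ms), `u`, `I`, `phi` (time x pixel
#'   matrices), `u_return`, `I_return`, `drive`.
#' @examples
#' lay <- build_hex_array(40, 200)
#' rm <- cross_resistance_matrix(lay, medium())
#' pp <- pixel_params(lay, rm)
#' drv <- project_pattern(lay, pattern_full_field(), 1, 10, 40, duration = 25)
#' tr <- simulate_array(drv, rm, pp)
#' @export
simulate_array <- function(drive, rmat, params, init = NULL, dt_out = 0.05,
                           rtol_V = 1e-6, dt_max = 1, dt_fixed = NULL,
                           conducting = NULL) {
  stopifnot(inherits(drive, "pv_drive"), inherits(rmat, "pv_rmatrix"))
  if (drive$duration <= 0) stop("drive duration must be positive")
  n <- length(drive$mask1)
  if (is.null(init)) init <- initial_state(drive$layout)

  # event times: pulse onsets/offsets and reversals, ms
  period <- 1000 / drive$rate
  on <- pulse_onsets(drive)
  ev <- sort(unique(c(0, on, on + drive$pulse_width,
                      if (is.finite(drive$reversal_period))
                        seq(0, drive$duration, by = drive$reversal_period),
                      drive$duration)))
  ev <- ev[ev <= drive$duration + 1e-12]

  t_out <- seq(0, drive$duration, by = dt_out)
  n_out <- length(t_out)
  U <- matrix(NA_real_, n_out, n); II <- matrix(NA_real_, n_out, n)
  UR <- numeric(n_out)

  record <- local({
    # linear interpolation between accepted states onto the output grid
    last_t <- 0; last_state <- init; filled <- 0L
    U[1, ] <<- init$u; UR[1] <<- init$u_return; filled <- 1L
    function(t_new, s_new) {
      while (filled < n_out && t_out[filled + 1L] <= t_new + 1e-12) {
        w <- if (t_new > last_t) (t_out[filled + 1L] - last_t) / (t_new - last_t) else 1
        U[filled + 1L, ] <<- last_state$u + w * (s_new$u - last_state$u)
        UR[filled + 1L] <<- last_state$u_return + w * (s_new$u_return - last_state$u_return)
        filled <<- filled + 1L
      }
      last_t <<- t_new; last_state <<- s_new
      filled
    }
  })

  state <- init
  tcur <- 0
  h_ms <- if (is.null(dt_fixed)) min(dt_max, drive$pulse_width / 10) else dt_fixed
  while (tcur < drive$duration - 1e-12) {
    seg_end <- ev[which(ev > tcur + 1e-12)[1]]
    irr <- drive_irradiance(drive, tcur + 1e-9)   # constant within the segment
    while (tcur < seg_end - 1e-12) {
      h <- min(h_ms, seg_end - tcur)
      if (!is.null(dt_fixed)) {
        st <- be_step_masked(state, irr, rmat, params, h * 1e-3, conducting)
        state <- st$state
        tcur <- tcur + h
        record(tcur, state)
        next
      }
      # step doubling error control
      full <- be_step_masked(state, irr, rmat, params, h * 1e-3, conducting)
      half1 <- be_step_masked(state, irr, rmat, params, h * 5e-4, conducting)
      half2 <- be_step_masked(half1$state, irr, rmat, params, h * 5e-4, conducting)
      err <- max(abs(full$state$u - half2$state$u),
                 abs(full$state$u_return - half2$state$u_return))
      if (err <= rtol_V || h <= 1e-6) {
        state <- half2$state
        tcur <- tcur + h
        record(tcur, state)
        fac <- if (err > 0) min(2, max(0.5, 0.9 * sqrt(rtol_V / err))) else 2
        h_ms <- min(dt_max, h * fac)
      } else {
        h_ms <- max(h / 2, 1e-6)
        if (h_ms <= 1e-6 && err > 100 * rtol_V)
          stop("step-size underflow: the system is too stiff at t = ",
               signif(tcur, 6), " ms (local error ", signif(err, 3), " V)")
      }
    }
  }

  # currents on the output grid from the recorded voltages
  PHI <- matrix(NA_real_, n_out, n)
  for (k in seq_len(n_out)) {
    irr <- drive_irradiance(drive, t_out[k] + 1e-9)
    sol <- solve_network_currents(U[k, ], irr, rmat, params, u_return = UR[k],
                                  conducting = conducting)
    II[k, ] <- sol$I
    PHI[k, ] <- sol$phi
  }
  structure(list(t = t_out, u = U, I = II, phi = PHI,
                 u_return = UR, I_return = -rowSums(II), drive = drive,
                 rmat = rmat, params = params),
            class = "pv_trace")
}

be_step_masked <- function(state, irr, rmat, params, h, conducting) {
  n <- length(state$u)
  aug <- diag(rep(h / params$C_active, n)) + h / params$C_return
  sol <- solve_network_currents(state$u, irr, rmat, params,
                                u_return = state$u_return, coupling = aug,
                                conducting = conducting)
  list(state = structure(list(u = state$u + h * sol$I / params$C_active,
                              u_return = state$u_return - h * sum(sol$I) / params$C_return),
                         class = "pv_state"),
       I = sol$I)
}

#' @export
print.pv_trace <- function(x, ...) {
  cat(sprintf("<pv_trace> %d pixels, %g ms (%d samples), peak |I| %.3g uA\n",
              ncol(x$u), max(x$t), length(x$t), max(abs(x$I)) * 1e6))
  invisible(x)
}

#' Drive a periodic stimulus to its steady state
#'
#' Repeats the (periodic) drive until the interface voltages at the period
#' boundaries change by less than `tol_uV`, then returns the trace of the last
#' period together with the converged initial state.
#'
#' @param drive A `pv_drive` whose `duration` equals one period.
#' @param rmat,params,init,conducting,... Passed to [simulate_array()].
#' @param tol_uV Convergence tolerance on interface voltages, uV.
#' @param max_periods Iteration cap.
#' @return A `pv_trace` (attributes: `periods`, `converged`, `state0`).
#' @export
run_to_steady_state <- function(drive, rmat, params, init = NULL,
                                tol_uV = 10, max_periods = 200,
                                conducting = NULL, ...) {
  state <- if (is.null(init)) initial_state(drive$layout) else init
  tr <- NULL
  for (p in seq_len(max_periods)) {
    u0 <- state$u; ur0 <- state$u_return
    tr <- simulate_array(drive, rmat, params, init = state,
                         conducting = conducting, ...)
    m <- length(tr$t)
    state <- structure(list(u = tr$u[m, ], u_return = tr$u_return[m]),
                       class = "pv_state")
    dmax <- max(abs(state$u - u0), abs(state$u_return - ur0))
    if (dmax < tol_uV * 1e-6) {
      attr(tr, "periods") <- p
      attr(tr, "converged") <- TRUE
      attr(tr, "state0") <- state
      return(tr)
    }
  }
  stop("no steady state within ", max_periods,
       " periods (last period-to-period change ", signif(dmax, 3), " V)")
}
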
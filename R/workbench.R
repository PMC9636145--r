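# End-to-end experiment runners and configuration plumbing.

#' Near-field potential waveform above the array
#'
#' Electrolyte potential at a probe point (e.g. a micropipette 20 um above a
#' pixel) for every sample of a simulation trace.
#'
#' @param trace A `pv_trace`.
#' @param point Probe position `(x, y, z)`, um.
#' @return Data frame with `t_ms` and `v` (volts).
#' @export
near_field_waveform <- function(trace, point) {
  rmat <- trace$rmat
  kern <- step_kernels(rmat, point[3])[[1]]
  cen <- rmat$layout$centers
  d <- sqrt((point[1] - cen[, 1])^2 + (point[2] - cen[, 2])^2) * 1e-6
  kvec <- kern(d)
  ms <- medium_si(rmat$medium)
  ringv <- annulus_pot(sqrt(sum(point[1:2]^2)) * 1e-6, point[3] * 1e-6,
                       rmat$layout$return_inner * 1e-6,
                       rmat$layout$return_outer * 1e-6, ms)
  v <- drop(trace$I %*% kvec) + trace$I_return * ringv
  data.frame(t_ms = trace$t, v = v)
}

#' Grating-contrast experiment
#'
#' The central field-confinement computation: alternate rows of the array are
#' illuminated, dark-pixel interfaces carry a pre-charge, and the
#' trans-cellular potential step is evaluated at the moment of the peak
#' bright-row step — the pulse onset, before the interfaces charge and the
#' injected currents sag. Dark pixels act either as `"transient_return"`
#' (their diode conduction is part of the network solve) or as
#' `"nonconductive"` (current pinned at zero, the idealization of a bias far
#' below the diode turn-on).
#'
#' @param pixel_width Pixel width, um.
#' @param array_diameter Device diameter, um.
#' @param peak_irradiance Bright-row irradiance, mW/mm^2.
#' @param dark_bias Dark-pixel interface pre-charge, V.
#' @param dark_role `"transient_return"` or `"nonconductive"`.
#' @param bright_bias Bright-pixel interface voltage at pulse onset, V.
#' @param med A `pv_medium`; the tissue stack by default.
#' @param raster Also compute row-raster means.
#' @return List with `contrast` (a `pv_contrast`), `currents` (A),
#'   `step` (from [transcellular_step()]), `layout`, `rmat`.
#' @export
grating_contrast_experiment <- function(pixel_width = 40, array_diameter = 1500,
                                        peak_irradiance = 1, dark_bias = 0.2,
                                        dark_role = c("transient_return",
                                                      "nonconductive"),
                                        bright_bias = 0, med = tissue_medium(),
                                        raster = FALSE) {
  dark_role <- match.arg(dark_role)
  layout <- build_hex_array(pixel_width, array_diameter)
  rmat <- cross_resistance_matrix(layout, med)
  params <- pixel_params(layout, rmat)
  pat <- pattern_grating(bar_width = layout$row_pitch)
  bright <- pattern_weights(pat, layout) > 0.5
  u <- ifelse(bright, bright_bias, dark_bias)
  conducting <- if (dark_role == "nonconductive") bright else NULL
  sol <- solve_network_currents(u, ifelse(bright, peak_irradiance, 0),
                                rmat, params, conducting = conducting)
  st <- transcellular_step(sol$I, rmat,
                           at = if (raster) "raster" else "centers")
  ct <- grating_contrast(st, pat, layout)
  list(contrast = ct, currents = sol$I, step = st, layout = layout,
       rmat = rmat, params = params, dark_role = dark_role,
       dark_bias = dark_bias)
}

#' Field-stop closure experiment
#'
#' Drives the array to steady state under full-field pulsing, then closes an
#' octagonal field stop between two pulses and follows the transition. The
#' probe reports the near-field potential above a pixel left in shadow: after
#' closure the first pulse shows a cathodic dip as the shaded, still-charged
#' pixels discharge into the electrolyte as transient returns.
#'
#' @param pixel_width,array_diameter Geometry, um.
#' @param stop_width Octagon width across flats, um.
#' @param peak_irradiance Irradiance, mW/mm^2.
#' @param pulse_width Pulse width, ms.
#' @param rate Repetition rate, Hz.
#' @param n_post Pulses simulated after closure.
#' @param med A `pv_medium` (homogeneous electrolyte by default: the
#'   experiment emulates a saline bath).
#' @param probe_z Probe height, um.
#' @param ... Passed to the integrator.
#' @return List with `pre` and `post` (`pv_trace`s), `probe` (data frame,
#'   time relative to closure), `probe_pixel`.
#' @export
field_stop_experiment <- function(pixel_width = 40, array_diameter = 500,
                                  stop_width = NULL, peak_irradiance = 8,
                                  pulse_width = 10, rate = 40, n_post = 3,
                                  med = medium(), probe_z = 20, ...) {
  if (is.null(stop_width)) stop_width <- array_diameter * 2 / 3
  layout <- build_hex_array(pixel_width, array_diameter)
  rmat <- cross_resistance_matrix(layout, med)
  params <- pixel_params(layout, rmat)
  period <- 1000 / rate

  full <- project_pattern(layout, pattern_full_field(), peak_irradiance,
                          pulse_width, rate, duration = period)
  pre <- run_to_steady_state(full, rmat, params, ...)
  state <- attr(pre, "state0")

  oct <- pattern_field_stop(stop_width)
  shaded <- pattern_weights(oct, layout) == 0
  if (!any(shaded)) stop("field stop covers the whole array; nothing is shaded")
  post_drive <- project_pattern(layout, oct, peak_irradiance, pulse_width,
                                rate, duration = n_post * period)
  post <- simulate_array(post_drive, rmat, params, init = state, ...)

  # probe above the shaded pixel closest to the stop edge
  w2 <- stop_width / 2
  cen <- layout$centers
  margin <- pmax(abs(cen[, 1]), abs(cen[, 2]), (abs(cen[, 1]) + abs(cen[, 2])) / sqrt(2)) - w2
  cand <- which(shaded)
  probe_pixel <- cand[which.min(margin[cand])]
  pt <- c(cen[probe_pixel, ], probe_z)
  pr_pre <- near_field_waveform(pre, pt)
  pr_post <- near_field_waveform(post, pt)
  probe <- rbind(data.frame(t_ms = pr_pre$t_ms - max(pr_pre$t_ms), v = pr_pre$v),
                 data.frame(t_ms = pr_post$t_ms, v = pr_post$v))
  list(pre = pre, post = post, probe = probe, probe_pixel = probe_pixel,
       layout = layout, rmat = rmat, params = params)
}

# ---- configuration ----------------------------------------------------------

#' Default experiment configuration
#'
#' @param experiment One of `"safety_arithmetic"`, `"grating_contrast"`,
#'   `"field_stop"`, `"frequency_sweep"`, `"acuity_recovery"`.
#' @param seed Integer seed recorded (and used) by the run.
#' @return A nested configuration list.
#' @export
default_config <- function(experiment = "safety_arithmetic", seed = 1L) {
  list(
    experiment = experiment,
    seed = as.integer(seed),
    geometry = list(pixel_width = 40, array_diameter = 1500),
    # tissue stack for the in-tissue contrast experiment; homogeneous
    # electrolyte for the bench-style protocols
    medium = list(resistivity = 700,
                  layer_thickness = if (experiment == "grating_contrast") 90 else NULL,
                  resistivity_above = 55),
    protocol = list(peak_irradiance = 1, pulse_width = 10, rate = 40,
                    reversal_period = 500, dark_bias = c(0.2, 0.5),
                    stop_width = 330, rates = c(1, 2, 5, 10, 20, 40, 64, 125)),
    stats = list(alpha = 0.05, ci_mult = 1.92, um_per_degree = 64.3),
    synth = list(bar_widths = c(157, 104, 78, 52, 39, 26, 20, 13),
                 n_animals = 5)
  )
}

#' Validate an experiment configuration
#'
#' Structural and physical checks; returns issues instead of raising.
#'
#' @param config A configuration list (see [default_config()]).
#' @return Character vector of issues; empty when the config is runnable.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  addi <- function(msg) issues <<- c(issues, msg)
  if (!is.list(config) || is.null(config$experiment)) {
    return("config$experiment is missing")
  }
  known <- c("safety_arithmetic", "grating_contrast", "field_stop",
             "frequency_sweep", "acuity_recovery")
  if (!config$experiment %in% known)
    addi(paste0("config$experiment: unknown experiment '", config$experiment, "'"))
  g <- config$geometry
  if (is.null(g$pixel_width) || g$pixel_width <= 0)
    addi("config$geometry$pixel_width: must be positive")
  if (is.null(g$array_diameter) || g$array_diameter <= 0)
    addi("config$geometry$array_diameter: must be positive")
  m <- config$medium
  if (!is.null(m) && (!is.null(m$resistivity) && m$resistivity <= 0))
    addi("config$medium$resistivity: must be positive")
  p <- config$protocol
  if (!is.null(p$pulse_width) && !is.null(p$rate) &&
      p$pulse_width >= 1000 / p$rate)
    addi("config$protocol: pulse_width must be shorter than the pulse period")
  if (!is.null(p$peak_irradiance) && p$peak_irradiance < 0)
    addi("config$protocol$peak_irradiance: must be nonnegative")
  issues
}

#' Read / write configurations as YAML or JSON
#' @param file Path ending in `.yaml`, `.yml` or `.json`.
#' @param config A configuration list.
#' @return `read_config` returns the list; `write_config` returns `file`.
#' @export
read_config <- function(file) {
  if (grepl("\\.json$", file)) jsonlite::fromJSON(file, simplifyVector = TRUE)
  else yaml::read_yaml(file)
}

#' @rdname read_config
#' @export
write_config <- function(config, file) {
  if (grepl("\\.json$", file))
    jsonlite::write_json(config, file, auto_unbox = TRUE, digits = NA, null = "null")
  else yaml::write_yaml(config, file)
  invisible(file)
}

#' Run a named experiment
#'
#' Executes one of the package's end-to-end pipelines and (optionally) writes
#' its outputs — a JSON summary, CSV tables and a resolved-config snapshot —
#' under `outdir`. Identical config and seed give identical outputs.
#'
#' @param config Configuration list (see [default_config()]).
#' @param outdir Output directory, or `NULL` to skip writing.
#' @param quiet Suppress progress messages.
#' @return The result list of the experiment, invisibly when writing.
#' @export
run_experiment <- function(config, outdir = NULL, quiet = FALSE) {
  issues <- validate_config(config)
  if (length(issues))
    stop("invalid config:\n", paste("-", issues, collapse = "\n"))
  set.seed(config$seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  g <- config$geometry; p <- config$protocol
  med <- if (is.null(config$medium$layer_thickness)) medium(config$medium$resistivity)
         else medium(config$medium$resistivity, config$medium$layer_thickness,
                     config$medium$resistivity_above)

  res <- switch(config$experiment,
    safety_arithmetic = {
      lay <- build_hex_array(g$pixel_width, g$array_diameter)
      pp <- pixel_params(lay)
      pc <- pulse_charge(1.2, 10, pp)
      say("charge density %.3g mC/cm^2, interface step %.3g V",
          pc$charge_density_mC_cm2, pc$voltage_step_V)
      c(pc, list(open_circuit_V = open_circuit_voltage(8, pp)))
    },
    grating_contrast = {
      biases <- p$dark_bias
      runs <- lapply(biases, function(b) {
        role <- if (b >= 0.35) "transient_return" else "nonconductive"
        say("contrast run: dark bias %.2f V (%s)", b, role)
        grating_contrast_experiment(g$pixel_width, g$array_diameter,
                                    p$peak_irradiance, dark_bias = b,
                                    dark_role = role, med = med)
      })
      names(runs) <- paste0("bias_", biases)
      list(runs = runs,
           contrast = vapply(runs, function(r) r$contrast$contrast, numeric(1)))
    },
    field_stop = {
      field_stop_experiment(g$pixel_width, min(g$array_diameter, 500),
                            stop_width = p$stop_width,
                            peak_irradiance = 8, pulse_width = p$pulse_width,
                            rate = p$rate, med = med)
    },
    frequency_sweep = {
      lay <- build_hex_array(g$pixel_width, min(g$array_diameter, 400))
      rm_ <- cross_resistance_matrix(lay, med)
      pp <- pixel_params(lay, rm_)
      frequency_sweep(p$rates, lay, rm_, pp, peak_irradiance = 1.2,
                      pulse_width = 4)
    },
    acuity_recovery = {
      gp <- vep_generator_params()
      vs <- synth_recording(gp, c(config$synth$bar_widths, rep(Inf, 2)),
                            n_animals = config$synth$n_animals,
                            seed = config$seed)
      amps <- measure_amplitudes(vs)
      nf <- noise_floor(vs)
      est <- fit_acuity(amps[is.finite(amps$bar_width), ], nf,
                        alpha = config$stats$alpha,
                        ci_mult = config$stats$ci_mult,
                        um_per_degree = config$stats$um_per_degree)
      list(estimate = est, amplitudes = amps, noise = nf,
           true_acuity_um = gp$acuity_um)
    },
    stop("unreachable")
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(outdir, "config.json"))
    summary <- experiment_summary(config$experiment, res)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    if (config$experiment == "frequency_sweep")
      write.csv(res, file.path(outdir, "sweep.csv"), row.names = FALSE)
    if (config$experiment == "acuity_recovery")
      write.csv(res$amplitudes, file.path(outdir, "amplitudes.csv"),
                row.names = FALSE)
    return(invisible(res))
  }
  res
}

experiment_summary <- function(experiment, res) {
  switch(experiment,
    safety_arithmetic = list(
      charge_density_mC_cm2 = res$charge_density_mC_cm2,
      voltage_step_V = res$voltage_step_V,
      open_circuit_V = res$open_circuit_V),
    grating_contrast = list(contrast_pct = as.list(res$contrast)),
    field_stop = list(
      min_probe_mV_post = min(res$probe$v[res$probe$t_ms >= 0]) * 1e3),
    frequency_sweep = list(rates_Hz = res$rate_Hz, normalized = res$normalized),
    acuity_recovery = list(
      acuity_um = res$estimate$acuity_um,
      sd_um = res$estimate$sd_um,
      ci95_um = res$estimate$ci95_um,
      true_acuity_um = res$true_acuity_um),
    list())
}

#' Export a simulation trace as long-format CSV
#' @param trace A `pv_trace`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trace_csv <- function(trace, file) {
  n <- ncol(trace$u)
  df <- data.frame(t_ms = rep(trace$t, n),
                   pixel = rep(seq_len(n), each = length(trace$t)),
                   u_V = as.vector(trace$u), I_A = as.vector(trace$I),
                   phi_V = as.vector(trace$phi))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
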
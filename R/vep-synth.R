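# Synthetic sweep-VEP recordings: the statistical structure the acuity
# estimator assumes, so the pipeline is testable without animal data.

#' Generator parameters for synthetic VEP recordings
#'
#' The reversal-response amplitude follows the log-linear law
#' `A(s) = beta0 + beta1 * log(s)` (s = grating density, 1/um; `beta1 < 0`
#' so the response declines toward fine gratings), floored at zero. The
#' defaults put the amplitude at the noise floor (8.89 uV) at a bar width of
#' 30 um and give responses of a few tens of microvolts at coarse gratings —
#' the magnitudes seen in cortical recordings. Per-animal variability enters
#' through an intercept jitter and a per-animal noise level.
#'
#' @param beta1 Slope of the amplitude law, uV per log-unit of density.
#' @param acuity_um Bar width at which the mean amplitude law crosses the mean
#'   noise floor, um (fixes `beta0`).
#' @param noise_floor_mean,noise_floor_sd Mean and across-animal SD of the
#'   measured noise floor, uV.
#' @param animal_sd Across-animal SD of the amplitude about the law, uV.
#' @param n_trials Trials averaged per recording.
#' @param fs Sampling rate, Hz.
#' @param carrier Pulse carrier rate, Hz.
#' @param pulse_width Carrier pulse width, ms.
#' @param reversal_ms Grating reversal period, ms.
#' @param duration_ms Recording length, ms.
#' @param artifact_uV Stimulus-artifact amplitude riding at the carrier, uV.
#' @param n1_ms,n2_ms Latencies of the two deflections of the biphasic
#'   response template, ms (dominant deflection within 0-100 ms).
#' @return A `pv_vepgen` parameter list (includes the derived `beta0` and the
#'   per-trial noise SD implied by the noise floor).
#' @export
vep_generator_params <- function(beta1 = -12, acuity_um = 30,
                                 noise_floor_mean = 8.89, noise_floor_sd = 2.52,
                                 animal_sd = 3, n_trials = 250, fs = 2000,
                                 carrier = 64, pulse_width = 4,
                                 reversal_ms = 500, duration_ms = 4000,
                                 artifact_uV = 20, n1_ms = 35, n2_ms = 70,
                                 trial_noise_sd = NULL) {
  stopifnot(acuity_um > 0, noise_floor_mean > 0, n_trials >= 1, fs > 0)
  beta0 <- noise_floor_mean - beta1 * log(1 / acuity_um)
  # per-trial noise SD such that the expected max-min of the trial-averaged
  # residual noise over the 0-100 ms window equals the target floor; an
  # explicit trial_noise_sd (e.g. 0 for noiseless checks) overrides it
  n_win <- round(0.1 * fs)
  sigma_res <- if (is.null(trial_noise_sd))
    noise_floor_mean / expected_gaussian_range(n_win)
  else trial_noise_sd / sqrt(n_trials)
  structure(list(beta0 = beta0, beta1 = beta1, acuity_um = acuity_um,
                 noise_floor_mean = noise_floor_mean,
                 noise_floor_sd = noise_floor_sd, animal_sd = animal_sd,
                 trial_noise_sd = sigma_res * sqrt(n_trials),
                 n_trials = n_trials, fs = fs, carrier = carrier,
                 pulse_width = pulse_width, reversal_ms = reversal_ms,
                 duration_ms = duration_ms, artifact_uV = artifact_uV,
                 n1_ms = n1_ms, n2_ms = n2_ms), class = "pv_vepgen")
}

#' Amplitude law of the generator
#' @param params A `pv_vepgen`.
#' @param s Grating density, 1/um.
#' @return Mean reversal-response amplitude, uV (floored at zero).
#' @export
vep_amplitude_law <- function(params, s) {
  pmax(params$beta0 + params$beta1 * log(s), 0)
}

# E[max - min] of n iid standard normals (exact order-statistic integral)
expected_gaussian_range <- function(n) {
  f <- function(x) 1 - stats::pnorm(x)^n - (1 - stats::pnorm(x))^n
  integrate(f, -12, 12, rel.tol = 1e-10)$value
}

# biphasic reversal-response template, unit peak-to-peak within the 0-100 ms
# window, zero before the reversal
vep_template <- function(params, t_ms) {
  shape <- function(t, t0, tau) ifelse(t > 0, (t / t0)^2 * exp(-t / tau), 0)
  w <- -shape(t_ms, params$n1_ms / 2, params$n1_ms / 2) +
    0.6 * shape(t_ms - params$n1_ms, params$n2_ms / 3, params$n2_ms / 3)
  win <- t_ms >= 0 & t_ms <= 100
  p2p <- max(w[win]) - min(w[win])
  w / p2p
}

# stimulus-locked carrier artifact: one pulse-shaped lobe per carrier period
carrier_artifact <- function(t_ms, carrier, pulse_width, amp_uV) {
  period <- 1000 / carrier
  tm <- t_ms %% period
  lobe <- ifelse(tm < pulse_width, 1, -0.35 * exp(-(tm - pulse_width) / 2))
  amp_uV * lobe
}

# reversal-locked response template tiled over the whole recording and made
# exactly invariant under the analysis pipeline: orthogonal to the artifact
# template and untouched by the carrier notches (alternating projections).
# With this construction the noiseless pipeline returns A(s) exactly.
tiled_response_template <- function(params, t_ms) {
  v <- vep_template(params, t_ms %% params$reversal_ms)
  art <- carrier_artifact(t_ms, params$carrier, params$pulse_width, 1)
  # project into the notch-free subspace, then orthogonalize against the
  # notch-free part of the artifact; the notch band and its complement are
  # orthogonal, so the result is exactly invariant under both pipeline steps
  v <- spectral_clean(v, params$fs, params$carrier)
  a1 <- spectral_clean(art, params$fs, params$carrier)
  v <- v - sum(v * a1) / sum(a1^2) * a1
  # unit peak-to-peak over the first 0-100 ms window, matching the
  # sample-index convention of reversal_amplitude()
  win1 <- t_ms < 100
  v / (max(v[win1]) - min(v[win1]))
}

#' Synthesize sweep-VEP recordings
#'
#' For every animal and bar width, builds the trial-averaged trace
#' `A(s) * template(t mod reversal) + artifact * carrier(t) + residual noise`,
#' where the residual noise SD is the per-trial SD divided by `sqrt(n_trials)`.
#' `bar_width = Inf` denotes a static-grating (noise-floor) recording: no
#' reversal response, everything else identical. Reproducible for a given
#' seed.
#'
#' @param params A `pv_vepgen`.
#' @param bar_widths Grating bar widths, um (may include `Inf` for static).
#' @param n_animals Number of simulated animals.
#' @param seed Integer seed.
#' @return A `pv_vepset`: list with `recordings` (list of lists: `trace` (uV),
#'   `t_ms`, `bar_width`, `animal`, `true_amplitude`), `params`, `seed`.
#' @examples
#' g <- vep_generator_params()
#' vs <- synth_recording(g, c(157, 78, 39), n_animals = 2, seed = 1)
#' @export
synth_recording <- function(params, bar_widths, n_animals = 5, seed = 1) {
  stopifnot(inherits(params, "pv_vepgen"))
  if (!length(bar_widths)) stop("bar_widths must be non-empty")
  if (any(bar_widths <= 0)) stop("bar_widths must be positive")
  set.seed(seed)
  t_ms <- seq(0, params$duration_ms - 1000 / params$fs, by = 1000 / params$fs)
  tmpl <- tiled_response_template(params, t_ms)
  art <- carrier_artifact(t_ms, params$carrier, params$pulse_width,
                          params$artifact_uV)
  sig_res <- params$trial_noise_sd / sqrt(params$n_trials)
  recs <- list()
  for (an in seq_len(n_animals)) {
    a_jit <- rnorm(1, 0, params$animal_sd)
    floor_an <- rnorm(1, params$noise_floor_mean, params$noise_floor_sd)
    scale_an <- floor_an / params$noise_floor_mean
    for (bw in bar_widths) {
      amp <- if (is.finite(bw))
        max(vep_amplitude_law(params, 1 / bw) + a_jit, 0) else 0
      noise <- rnorm(length(t_ms), 0, sig_res * scale_an)
      recs[[length(recs) + 1L]] <- list(
        trace = amp * tmpl * is.finite(bw) + art + noise,
        t_ms = t_ms, bar_width = bw, animal = an, true_amplitude = amp)
    }
  }
  structure(list(recordings = recs, params = params, seed = seed,
                 n_animals = n_animals), class = "pv_vepset")
}

#' @export
print.pv_vepset <- function(x, ...) {
  bw <- vapply(x$recordings, function(r) r$bar_width, numeric(1))
  cat(sprintf("<pv_vepset> %d recordings (%d animals), bar widths: %s um\n",
              length(x$recordings), x$n_animals,
              paste(sort(unique(bw)), collapse = ", ")))
  invisible(x)
}

#' Draw amplitude-level sweep data from the generator's statistical model
#'
#' The distributional model that [fit_acuity()] assumes, without the
#' trace-level plumbing: per animal and bar width an amplitude
#' `A(s) + N(0, animal_sd)`, and per noise recording a floor value
#' `N(noise_floor_mean, noise_floor_sd)`. The peak-to-peak statistic on full
#' traces is biased upward by residual noise (a range statistic); this
#' amplitude-level path is the reference model for confidence-interval
#' calibration, while trace-level recovery is checked against its own
#' noise-predicted tolerance.
#'
#' @param params A `pv_vepgen`.
#' @param bar_widths Bar widths, um.
#' @param n_animals Animals per bar width.
#' @param n_noise Noise-floor recordings.
#' @param seed Integer seed.
#' @return List with `amplitudes` (data frame `bar_width`, `animal`,
#'   `amplitude`) and `noise` (a `pv_noise_floor`).
#' @export
synth_amplitudes <- function(params, bar_widths, n_animals = 5, n_noise = 10,
                             seed = 1) {
  stopifnot(inherits(params, "pv_vepgen"))
  if (!length(bar_widths)) stop("bar_widths must be non-empty")
  set.seed(seed)
  df <- expand.grid(animal = seq_len(n_animals), bar_width = bar_widths)
  df$amplitude <- vep_amplitude_law(params, 1 / df$bar_width) +
    rnorm(nrow(df), 0, params$animal_sd)
  nv <- rnorm(n_noise, params$noise_floor_mean, params$noise_floor_sd)
  list(amplitudes = df[, c("bar_width", "animal", "amplitude")],
       noise = noise_floor(nv))
}

#' Synthetic corneal stimulus-artifact template
#'
#' Stimulus-locked waveform used for template subtraction of the artifact.
#' Either a canonical pulse-locked lobe train, or (via `trace`/`coeffs`) the
#' simulator's own far-field waveform resampled onto the recording clock.
#'
#' @param pulse_width Pulse width, ms.
#' @param rate Carrier rate, Hz.
#' @param duration_ms Template length, ms.
#' @param fs Sampling rate, Hz.
#' @param amplitude Artifact amplitude, uV.
#' @param trace Optional `pv_trace`; if given, the template is the far-field
#'   waveform of this simulation resampled to `fs`.
#' @return Numeric vector, uV.
#' @export
synth_corneal_template <- function(pulse_width = 4, rate = 64,
                                   duration_ms = 4000, fs = 2000,
                                   amplitude = 1, trace = NULL) {
  t_ms <- seq(0, duration_ms - 1000 / fs, by = 1000 / fs)
  if (!is.null(trace)) {
    ff <- far_field_waveform(trace)
    period <- 1000 / trace$drive$rate
    v <- approx(ff$t_ms, ff$v, xout = pmin(t_ms %% period, max(ff$t_ms)),
                rule = 2)$y
    return(v * amplitude)
  }
  carrier_artifact(t_ms, rate, pulse_width, amplitude)
}

#' Export a VEP set as long-format CSV
#' @param vepset A `pv_vepset`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_vepset_csv <- function(vepset, file) {
  df <- do.call(rbind, lapply(seq_along(vepset$recordings), function(i) {
    r <- vepset$recordings[[i]]
    data.frame(recording = i, animal = r$animal, bar_width_um = r$bar_width,
               t_ms = r$t_ms, uV = r$trace)
  }))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
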
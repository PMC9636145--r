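# Sweep-VEP grating-acuity pipeline: artifact template subtraction, carrier
# notching, peak-to-peak reversal amplitudes, noise floor, log-linear fit and
# the noise-intersection acuity with a delta-method confidence interval.

#' Remove the stimulus artifact with a corneal template
#'
#' Subtracts the least-squares-scaled template from the trace; the residual is
#' orthogonal to the template.
#'
#' @param trace Numeric vector (uV).
#' @param template Numeric vector of the same length.
#' @return The cleaned trace.
#' @export
remove_artifact <- function(trace, template) {
  if (length(trace) != length(template))
    stop("trace and template must have equal length")
  nrm <- sum(template^2)
  if (nrm == 0) stop("template has zero norm")
  trace - (sum(trace * template) / nrm) * template
}

#' Spectral cleaning of the carrier and its harmonics
#'
#' Spectrum-reconstruction filter: the trace is Fourier transformed, bins
#' within `bandwidth` of every harmonic of the carrier are zeroed, and the
#' trace is rebuilt by the inverse transform. The sub-carrier band (the 2 Hz
#' reversal response) passes with negligible distortion.
#'
#' @param trace Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param carrier Carrier rate, Hz (must be below Nyquist).
#' @param bandwidth Half-width of each notch, Hz.
#' @return The filtered trace.
#' @export
spectral_clean <- function(trace, fs, carrier = 64, bandwidth = 2) {
  n <- length(trace)
  if (carrier >= fs / 2) stop("carrier must be below the Nyquist rate")
  if (n < 2 * fs / carrier) stop("trace shorter than two carrier periods")
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)          # two-sided
  sp <- fft(trace)
  harm <- seq(carrier, fs / 2, by = carrier)
  kill <- Reduce(`|`, lapply(harm, function(h) abs(freq - h) <= bandwidth))
  sp[kill] <- 0
  Re(fft(sp, inverse = TRUE)) / n
}

#' Peak-to-peak reversal amplitude
#'
#' `max - min` of the trace within a window after each pattern reversal
#' (default 0-100 ms), averaged over reversals — the amplitude definition used
#' for both alternating and static (noise-floor) gratings.
#'
#' @param trace Numeric vector (uV).
#' @param fs Sampling rate, Hz.
#' @param reversal_ms Reversal period, ms.
#' @param window Window after each reversal, ms.
#' @return Mean peak-to-peak amplitude, uV.
#' @export
reversal_amplitude <- function(trace, fs, reversal_ms = 500,
                               window = c(0, 100)) {
  if (diff(window) <= 0) stop("empty window")
  n <- length(trace)
  dur_ms <- n / fs * 1000
  if (window[2] > reversal_ms || window[2] > dur_ms)
    stop("window does not fit within the trace")
  starts <- seq(0, dur_ms - reversal_ms + 1e-9, by = reversal_ms)
  p2p <- vapply(starts, function(t0) {
    i0 <- floor((t0 + window[1]) / 1000 * fs) + 1
    i1 <- min(floor((t0 + window[2]) / 1000 * fs), n)
    seg <- trace[i0:i1]
    max(seg) - min(seg)
  }, numeric(1))
  mean(p2p)
}

# full per-recording amplitude pipeline
recording_amplitude <- function(rec, params, template = NULL) {
  tr <- rec$trace
  if (is.null(template))
    template <- carrier_artifact(rec$t_ms, params$carrier, params$pulse_width, 1)
  tr <- remove_artifact(tr, template)
  tr <- spectral_clean(tr, params$fs, params$carrier)
  reversal_amplitude(tr, params$fs, params$reversal_ms)
}

#' Measure amplitudes of a synthetic VEP set
#'
#' Applies artifact removal, spectral cleaning and reversal-amplitude
#' extraction to every recording.
#'
#' @param vepset A `pv_vepset`.
#' @param template Optional artifact template (default: the generator's
#'   unit-amplitude carrier lobe train).
#' @return Data frame with `bar_width`, `animal`, `amplitude` (uV),
#'   `true_amplitude`.
#' @export
measure_amplitudes <- function(vepset, template = NULL) {
  p <- vepset$params
  do.call(rbind, lapply(vepset$recordings, function(r) {
    data.frame(bar_width = r$bar_width, animal = r$animal,
               amplitude = recording_amplitude(r, p, template),
               true_amplitude = r$true_amplitude)
  }))
}

#' Noise floor from static-grating recordings
#'
#' Runs the same amplitude pipeline on static-grating (or otherwise
#' response-free) recordings and summarizes across recordings/animals.
#'
#' @param x Either a numeric vector of noise amplitudes (uV) or a `pv_vepset`
#'   whose recordings have `bar_width = Inf`.
#' @param template Passed to [measure_amplitudes()] for a `pv_vepset`.
#' @return A `pv_noise_floor`: list with `mean`, `sd`, `n`, `values`.
#' @export
noise_floor <- function(x, template = NULL) {
  vals <- if (inherits(x, "pv_vepset")) {
    df <- measure_amplitudes(x, template)
    df$amplitude[!is.finite(df$bar_width)]
  } else as.numeric(x)
  if (length(vals) < 2) stop("need at least 2 noise recordings")
  structure(list(mean = mean(vals), sd = sd(vals), n = length(vals),
                 values = vals), class = "pv_noise_floor")
}

#' @export
print.pv_noise_floor <- function(x, ...) {
  cat(sprintf("<pv_noise_floor> %.3g +/- %.3g uV (n = %d)\n", x$mean, x$sd, x$n))
  invisible(x)
}

# Welch two-sample t test from summary statistics
welch_p <- function(m1, s1, n1, m2, s2, n2) {
  if (s1 == 0 && s2 == 0) return(if (m1 > m2) 0 else 1)
  se2 <- s1^2 / n1 + s2^2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (s1^4 / (n1^2 * (n1 - 1)) + s2^4 / (n2^2 * (n2 - 1)))
  stats::pt(tstat, df, lower.tail = FALSE)   # one-sided: amplitude above noise
}

#' Fit the grating acuity from amplitude-versus-density data
#'
#' The sweep-VEP acuity estimator: (1) keep bar widths whose amplitudes exceed
#' the noise floor (unpaired one-sided t test at `alpha`); (2) fit
#' `A = beta0 + beta1 log(s)` by least squares over the retained points
#' (`s` = 1/bar width, 1/um); (3) the acuity is the bar width at which the fit
#' crosses the noise-floor mean; (4) its standard deviation follows from the
#' delta method, combining the fit covariance with the variance of the noise
#' mean; (5) the confidence interval is `+/- ci_mult` standard deviations.
#'
#' @param amplitudes Data frame with columns `bar_width` (um) and `amplitude`
#'   (uV); several rows (animals/replicates) per bar width.
#' @param noise A `pv_noise_floor`.
#' @param alpha Significance level of the point-selection t test.
#' @param ci_mult Half-width of the confidence interval in standard
#'   deviations (1.92 by convention here).
#' @param noise_variance `"mean"` uses `sd^2 / n` (the variance of the noise
#'   mean); `"spread"` uses `sd^2` (the across-animal spread).
#' @param um_per_degree Retinal extent of one degree of visual angle, um.
#' @return A `pv_acuity`: `acuity_um`, `acuity_cpd`, `sd_um`, `ci95_um`,
#'   `beta` (intercept/slope), `cov`, `points_used`, `noise`.
#' @examples
#' amps <- data.frame(bar_width = rep(c(157, 78, 39), each = 3),
#'                    amplitude = rep(c(30, 22, 12), each = 3) + rnorm(9, 0, 0.5))
#' nf <- noise_floor(c(9.1, 8.4, 9.3, 8.6))
#' fit_acuity(amps, nf)
#' @export
fit_acuity <- function(amplitudes, noise, alpha = 0.05, ci_mult = 1.92,
                       noise_variance = c("mean", "spread"),
                       um_per_degree = 64.3) {
  noise_variance <- match.arg(noise_variance)
  stopifnot(is.data.frame(amplitudes),
            all(c("bar_width", "amplitude") %in% names(amplitudes)),
            inherits(noise, "pv_noise_floor"))
  amplitudes <- amplitudes[is.finite(amplitudes$bar_width), ]
  amplitudes$s <- 1 / amplitudes$bar_width

  # point selection: group mean significantly above the noise floor
  keep_bw <- vapply(split(amplitudes, amplitudes$bar_width), function(g) {
    p <- welch_p(mean(g$amplitude), if (nrow(g) > 1) sd(g$amplitude) else 0,
                 nrow(g), noise$mean, noise$sd, noise$n)
    p < alpha
  }, logical(1))
  used <- amplitudes$bar_width %in% as.numeric(names(keep_bw)[keep_bw])
  if (sum(keep_bw) < 2)
    stop("estimation impossible: fewer than 2 bar widths significantly above the noise floor")
  dat <- amplitudes[used, ]

  fit <- lm(amplitude ~ log(s), data = dat)
  beta <- coef(fit)
  if (!is.finite(beta[2]) || beta[2] >= 0)
    stop("no decline: fitted slope is nonnegative, acuity undefined")
  Sigma <- vcov(fit)
  if (any(!is.finite(Sigma))) Sigma <- matrix(0, 2, 2)   # exact (noiseless) fit

  ln_s_star <- unname((noise$mean - beta[1]) / beta[2])
  grad <- unname(c(-1 / beta[2], -ln_s_star / beta[2]))  # d ln s*/d beta
  var_noise <- if (noise_variance == "mean") noise$sd^2 / noise$n else noise$sd^2
  var_ln <- drop(t(grad) %*% Sigma %*% grad) + unname(var_noise / beta[2]^2)
  w <- exp(-ln_s_star)                                   # acuity as bar width, um
  sd_w <- w * sqrt(var_ln)
  ci <- c(w - ci_mult * sd_w, w + ci_mult * sd_w)

  structure(list(acuity_um = w, acuity_cpd = bar_width_to_cpd(w, um_per_degree),
                 sd_um = sd_w, ci95_um = ci, ci_mult = ci_mult,
                 beta = unname(beta), cov = Sigma,
                 points_used = sort(unique(dat$bar_width)),
                 noise = noise), class = "pv_acuity")
}

#' @export
print.pv_acuity <- function(x, ...) {
  cat(sprintf("<pv_acuity> %.1f um (%.2f cpd), sd %.2f um, CI [%.1f, %.1f] um (+/- %g sd)\n",
              x$acuity_um, x$acuity_cpd, x$sd_um, x$ci95_um[1], x$ci95_um[2],
              x$ci_mult))
  cat(sprintf("  fit: A = %.2f %+.2f log(s); points: %s um\n", x$beta[1],
              x$beta[2], paste(x$points_used, collapse = ", ")))
  invisible(x)
}

#' Convert between retinal bar width and angular grating frequency
#'
#' One grating cycle is two bar widths; `cpd = um_per_degree / (2 bar_width)`.
#' The conversion factor for the rat eye is 64.3 +/- 2.9 um per degree of
#' visual angle.
#'
#' @param bar_width_um Bar width, um.
#' @param cpd Grating frequency, cycles per degree.
#' @param um_per_degree Conversion factor, um/deg.
#' @param factor_sd Optional SD of the conversion factor for uncertainty
#'   propagation; if given, the result carries an `sd` attribute.
#' @return The converted value.
#' @examples
#' bar_width_to_cpd(27.9)    # 1.15 cpd
#' cpd_to_bar_width(1.0)     # 32.15 um
#' @export
bar_width_to_cpd <- function(bar_width_um, um_per_degree = 64.3, factor_sd = NULL) {
  if (any(bar_width_um <= 0)) stop("bar width must be positive")
  v <- um_per_degree / (2 * bar_width_um)
  if (!is.null(factor_sd)) attr(v, "sd") <- factor_sd / (2 * bar_width_um)
  v
}

#' @rdname bar_width_to_cpd
#' @export
cpd_to_bar_width <- function(cpd, um_per_degree = 64.3, factor_sd = NULL) {
  if (any(cpd <= 0)) stop("cpd must be positive")
  v <- um_per_degree / (2 * cpd)
  if (!is.null(factor_sd)) attr(v, "sd") <- factor_sd / (2 * cpd)
  v
}

#' JSON report of an acuity estimate
#' @param est A `pv_acuity`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_acuity_json <- function(est, file) {
  jsonlite::write_json(list(
    acuity_um = est$acuity_um, acuity_cpd = est$acuity_cpd,
    sd_um = est$sd_um, ci95_um = est$ci95_um, ci_mult = est$ci_mult,
    fit = list(intercept = est$beta[1], slope = est$beta[2],
               cov = as.vector(est$cov)),
    points_used_um = est$points_used,
    noise = list(mean = est$noise$mean, sd = est$noise$sd, n = est$noise$n)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
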
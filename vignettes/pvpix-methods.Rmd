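---
title: "Models and methods behind pvpix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pvpix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pvpix simulates planar monopolar photovoltaic arrays implanted under a
degenerate retina, and implements the sweep-VEP statistical pipeline used to
measure grating acuity from cortical recordings. This vignette describes the
models, their assumptions, the tunable parameters, and the numerical choices;
it states no empirical result that the package's tests and acceptance script
do not themselves compute.

## Volume conduction

The implant face is an insulating plane at `z = 0`; tissue or electrolyte
fills `z > 0`. Each active electrode is a disk of radius `a` carrying a
uniform current density (UCD): for the pulse widths of interest (4-10 ms,
much longer than the interface RC time) the capacitive electrode-electrolyte
interface distributes current uniformly rather than equipotentially. The
potential of a UCD disk per ampere is computed by radial quadrature of the
half-space point-source kernel `rho / (2 pi r)` (an elliptic-integral
reduction of the surface integral); on the axis it reduces to
`rho I (sqrt(a^2 + z^2) - z) / (pi a^2)`, and the disk-averaged self
potential — the UCD access resistance — is `8 rho / (3 pi^2 a)`. The
equipotential (EP) idealization, appropriate for the large common return, has
the classical spreading resistance `rho / (4 a)`.

**Media.** The default medium is a homogeneous half-space at 700 ohm-cm, a
value consistent both with retinal tissue and with phosphate-buffered saline
diluted to 10 percent by volume (the bench surrogate for retinal
resistivity). For in-tissue stimulation metrics the medium can carry a finite
retina layer over a vitreous half-space (`tissue_medium()`): the defaults are
a 90 um degenerate inner retina (about the span from the implant surface
through the inner plexiform layer and ganglion-cell layer in a
photoreceptor-degenerate rat) over 55 ohm-cm saline-like vitreous. Layered
potentials use the standard method-of-images reflection series with
coefficient `k = (rho_2 - rho_1) / (rho_2 + rho_1)`, truncated when
`|k|^n < 1e-6`; image terms treat each disk as a point source, exact to
`O((a / 2T)^2)`. The layered stack matters: a conductive vitreous forces
neighbour currents to cross the retina vertically, which is what limits
grating contrast above non-conducting dark pixels; a homogeneous half-space
understates that crosstalk. The homogeneous default is kept for bench-style
protocols, where the bath really is homogeneous.

**Return ring.** The common return is an annulus at the device rim (outer
radius = device radius; width 50 um, a geometry choice — only the ring's
coarse scale matters at the distances involved). It is modelled as a
uniformly distributed current sink; its self resistance comes from staggered
Gauss quadrature of the ring-ring kernel (staggering avoids the logarithmic
diagonal singularity).

**Cross-resistance matrix.** `cross_resistance_matrix()` assembles the
disk-averaged coupling of every electrode pair from a distance-splined mutual
profile (7-point average over the receiving disk; the profile is smooth so
200 spline nodes suffice), then references every potential to the return
surface with the ring folded in. Referencing to the return makes `R` a
two-terminal resistance matrix: symmetric by reciprocity (checked to 1e-6
relative in the tests, and exact by construction here), positive definite,
with diagonals close to the single-electrode UCD access resistance. Beyond
the splined range the disk kernel falls back to the analytic point source.

**FD oracle.** An independent finite-volume Poisson solver
(`fd_poisson_oracle()`) runs on a stretched tensor grid with a zero-flux
plane at `z = 0` (except over source disks), Dirichlet far boundaries about
ten array diameters out, and CHOLMOD sparse Cholesky for the solve. It is an
oracle only — tests require the semi-analytic kernels and the FD solution to
agree within 2-3 percent on single disks and a seven-disk cluster, and that
the discretization error at least halves when the grid spacing halves
(against analytic Dirichlet data, so only discretization error remains).

## Pixel circuit

Each pixel is a photocurrent source in parallel with one Si photodiode,
feeding the electrolyte through the interface capacitance of its active
electrode; all pixels share the return interface. Sign conventions (fixed
here, since they matter and are easy to flip): anodic current out of the
active electrode is positive; diode forward bias is active-terminal positive.
The instantaneous network satisfies

```
I_i = Iph_i - Idark(VD_i),     VD_i = u_i - u_ret + (R I)_i
```

with `Iph = responsivity x irradiance x photosensitive area` (0.51 A/W;
photosensitive area twice the electrode area), `Idark(V) = I0 (exp(V / n VT)
- 1)`, and `R` the cross-resistance matrix above. The diode defaults
(`I0 = 1.2e-12 A`, `n = 1.5`, `VT = 25.85 mV`) are calibrated to two
physical anchors: conduction of about 0.5 uA at 0.5 V (the turn-on knee at
stimulation-scale currents) and an open-circuit photovoltage at or below
0.6 V under strong illumination — the single-diode clamp that bounds every
voltage in the system. Faradaic leakage at the sputtered-iridium-oxide
interfaces is neglected (pure 6 mF/cm^2 capacitance); an optional shunt
conductance is off by default. The return capacitance is chosen so the
return RC equals 40 ms given the computed ring access resistance.

The nonlinear algebraic system is solved by damped Newton iteration to a
residual below 1e-13 A; the system is monotone (diode conductances are
positive, `R` is positive definite), so the solution is unique and Newton
with halving line search is globally convergent. The exponential is linearly
extended above 1.5 V so iterates cannot overflow; converged solutions sit far
below that bound.

**Dynamics.** Interface voltages evolve as `du_i/dt = I_i / C_active` (and
the return state with opposite net current). The integrator is implicit
(backward Euler): one implicit step is algebraically identical to a static
network solve with the coupling augmented by `h/C` terms, so stiffness never
limits the step. Steps adapt by step-doubling error control at 1e-6 V local
tolerance, with pulse edges as exact step boundaries. The contract is not a
particular integration scheme but agreement with a fixed-step 1 us
implicit-Euler reference within 1 percent RMS, which the tests enforce on
clusters up to 19 pixels. Periodic steady state is declared when interface
voltages at period boundaries move less than 10 uV.

**Transient returns.** A dark pixel whose interface was pre-charged near the
diode turn-on (`precondition()`) conducts on the next pulse and sinks current
from its lit neighbours — the optically controlled local return that confines
the field. At 0.2 V the same pixel conducts only a few percent of a bright
pixel's current; the contrast experiment exposes both treatments
(`dark_role = "transient_return"` solves the full network;
`"nonconductive"` pins dark currents at zero, the idealization of a bias far
below turn-on).

## Stimulation metrics

The activating-function proxy for bipolar-cell stimulation is the
trans-cellular potential step between 10 um above the implant (dendritic
end) and 57 um (axonal terminals in the mid inner plexiform layer). Grating
contrast compares mean steps over bright and dark rows of interior pixels
(at least two row pitches from the rim). Two figures are reported:

* `contrast` — the Michelson ratio `100 (Vb - Vd) / (Vb + Vd)`, the standard
  grating-contrast measure in vision science. It equals 100 exactly when the
  dark-row step reaches zero and exceeds 100 when dark rows are driven
  negative (and, being a ratio of sums, diverges if `Vd` approaches `-Vb`;
  values far above 100 simply mean strongly negative dark rows).
* `modulation` — the bright-relative ratio `100 (Vb - Vd) / Vb`, which maps
  Michelson `M` to `2M / (1 + M)`; reported alongside because the two are
  easy to conflate and only agree at 0 and 100.

Contrast is evaluated at the moment of the peak bright-row step, which is
the pulse onset: during the pulse the interfaces charge, diode shunting grows
and all currents sag, so the first instant is the extreme (the tests confirm
this on small arrays by full time integration). Pixel-centre sampling is
primary; row-raster means (4 um sampling along each interior row) are
available via `transcellular_step(at = "raster")`.

The far-field proxy `far_field_waveform()` replaces an anatomical eye/head
conduction model with fixed observer coefficients computed from the same
half-space kernels at a configurable observer (default on-axis, 5 mm). Only
the waveform shape and its rate dependence normalized at 1 Hz are meaningful;
absolute distant-electrode amplitudes would require the anatomical model and
are deliberately out of scope. The frequency sweep runs each rate to periodic
steady state; amplitudes decline with rate because shorter inter-pulse
intervals keep the interfaces charged and the diodes closer to conduction.
This collective mechanism needs realistic inter-pixel coupling: the tests run
it on a 43-pixel array, the smallest scale at which the trend is clean.

## Synthetic VEP recordings

`synth_recording()` emulates the statistics of sweep-VEP acquisitions at
2 kHz sampling: a reversal-locked biphasic response whose amplitude follows
`A(s) = beta0 + beta1 log(s)` in grating density `s` (1/bar-width), a
stimulus artifact at the 64 Hz pulse carrier, and Gaussian residual noise
scaled as per-trial noise over `sqrt(n_trials)`. Defaults put the amplitude
law at the noise floor (8.89 uV) at a 30 um bar width with slope -12 uV per
log-unit, giving tens of microvolts at coarse gratings; per-animal
variability enters through an intercept jitter (3 uV) and a per-animal noise
level drawn from the 8.89 +/- 2.52 uV floor distribution. The per-trial noise
SD is calibrated so that the expected windowed range of the averaged residual
noise equals the target floor, using the exact order-statistic integral for
the expected range of Gaussian samples.

Two constructions make the generator useful as ground truth:

* The tiled response template is projected into the carrier-notch-free
  subspace and orthogonalized against the artifact template (the two pipeline
  steps are orthogonal projections onto Fourier-complementary spaces, so the
  two-step construction is exact). A noiseless recording therefore passes
  through artifact removal and spectral cleaning untouched, and the pipeline
  recovers `A(s)` to machine precision — the estimator-consistency anchor.
* `synth_amplitudes()` draws from the amplitude-level model the fit assumes
  (Gaussian amplitudes about the law, Gaussian noise-floor values). The
  trace-level peak-to-peak statistic is a range statistic and is biased
  upward by residual noise — a property of the measurement definition, not a
  bug; on recordings it inflates every amplitude by several microvolts at
  these noise levels and shifts the noise-intersection toward finer
  gratings. On real recordings the same inflation affects the measured curve
  and the floor consistently, so the operational acuity (where the measured
  curve meets the measured floor) remains well defined; a latent amplitude
  law, which only a simulation has, is not the estimand of the trace-level
  procedure. Confidence-interval calibration is therefore assessed at the
  amplitude level, trace-level recovery against its own noise-predicted
  expectation. Passing tests show that the estimator is calibrated for data
  matching its statistical model and that the trace pipeline behaves as
  range-statistic theory predicts; they do not certify either against
  cortical data, whose noise is neither white nor stationary.

## Acuity estimation

`fit_acuity()` implements the sweep-VEP acuity convention: bar widths whose
amplitudes exceed the noise floor (one-sided Welch t test at alpha = 0.05,
group-mean vs noise replicates) enter an ordinary least-squares fit of
amplitude against `log(s)`; the acuity is the bar width where the fit crosses
the noise-floor mean; the delta method propagates the fit covariance and the
noise-mean variance (assumed independent) through the intersection:

```
ln s* = (m - b0) / b1
var(ln s*) = g' Cov(b) g + var(m) / b1^2,   g = (-1/b1, -ln s* / b1)
sd(w) = w sqrt(var(ln s*)),                 w = 1/s* (bar width, um)
```

The confidence interval is `w +/- 1.92 sd(w)`; 1.92 is used as the
convention here (configurable via `ci_mult`). `var(m)` defaults to the
variance of the noise mean (`sd^2/n`); the across-animal spread (`sd^2`) is
available via `noise_variance = "spread"`. Degenerate inputs raise targeted
errors: no points above the floor ("estimation impossible") and nonnegative
slopes ("no decline"). Conversions between retinal bar width and cycles per
degree use 64.3 um per degree of visual angle (rat eye), with optional
propagation of the +/- 2.9 um/deg factor uncertainty.

## Problem sizes and numerical choices

The package's own test and acceptance scales, chosen to exercise each claim
at the size it is made for: the full 1.5 mm, 40 um-pixel array (about 1275
pixels) for contrast and cross-resistance ranges; 7-19 pixel clusters for
integrator-versus-oracle equivalence; a 43-pixel array for the far-field rate
sweep; 500 Monte-Carlo replicates for interval coverage. Dense linear algebra
suffices for the circuit (an n x n solve per Newton step; about a second per
static solve at n = 1285), and the contrast experiment needs exactly one
static solve per bias condition since the peak is at pulse onset. Splines
over radial kernel profiles make field superposition O(n^2) with tiny
constants. Tolerances: Newton residual 1e-13 A, integrator local error
1e-6 V, steady state 10 uV, FD-versus-analytic 2-3 percent.

Interchange formats are plain text: CSV for layouts, traces and recordings,
JSON/YAML for configurations and reports.

## Known limitations

* The layered medium is a 1-D stack; no lateral inhomogeneity, no
  frequency-dependent (capacitive) bulk impedance, no anatomical eye or head
  geometry. Absolute far-field amplitudes are out of scope by design.
* The EP disk solution under a layered medium applies the image series to the
  homogeneous equipotential solution, which is approximate; EP mode is only
  used for the distant return, where the error is negligible.
* The circuit neglects Faradaic leakage and temperature dependence; the
  in-vitro reference-drift offset is a constant applied only when comparing
  to measured traces.
* The VEP generator emulates statistics, not cortical physiology; model
  mismatch between the log-linear law and real amplitude curves is exactly
  the situation the robustness fixtures (e.g. non-log-linear laws via custom
  amplitudes) are meant to probe.
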
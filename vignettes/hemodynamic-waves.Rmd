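---
title: "Modelling and measuring traveling hemodynamic waves in BOLD fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring traveling hemodynamic waves in BOLD fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemowave)
```

## The model

`hemowave` implements a linearized poroelastic model of cortical
hemodynamics. Cortical tissue is treated as an elastic porous medium whose
pores are the vasculature; blood flow, pressure, volume and deoxyhemoglobin
(dHb) are coupled fields on the two-dimensional cortical sheet. The chain
from neural activity $z(\mathbf r, t)$ to BOLD signal $y(\mathbf r, t)$ has
four stages:

1. **Flow regulation.** Arterial inflow $F$ responds to neural activity as
   a damped harmonic oscillator,
   $\ddot F + \kappa \dot F + \gamma F = \gamma\, a_F\, z$, with signal
   decay rate $\kappa$ (0.65 s$^{-1}$) and elimination constant $\gamma$
   (0.41 s$^{-2}$). The stage is normalized to unit zero-frequency gain so
   that the drive gain $a_F$ alone sets response amplitude.

2. **Blood-mass wave.** Conservation of blood mass
   ($\partial_t \xi = -\rho_f \nabla\!\cdot\!\mathbf v + F - c_P P$),
   conservation of momentum
   ($\rho_f\,\partial_t \mathbf v = -c_1 \nabla P - D\,\mathbf v$) and the
   constitutive vessel law $P = c_2\, \xi^{\beta}$ (reciprocal Grubb
   exponent $\beta = 1/0.38$), linearized about the resting state and with
   velocity and pressure eliminated, give a damped wave equation for the
   fractional blood-mass perturbation $v = \delta\xi/\xi_0$:
   $$\ddot v + 2\Gamma \dot v + \omega_D^2\, v - v_\beta^2 \nabla^2 v
     = \tfrac{1}{\tau}\big(\dot f + \tfrac{D}{\rho_f} f\big),$$
   with
   $$2\Gamma = \frac{\beta}{\tau} + \frac{D}{\rho_f}, \qquad
     v_\beta^2 = c_1 c_2\, \beta\, \xi_0^{\beta-1}, \qquad
     \omega_D^2 = \frac{\beta}{\tau}\cdot\frac{D}{\rho_f}.$$
   Damping thus splits into boundary outflow ($\beta/\tau$, where $\tau$
   is the mean transit time) and blood viscosity ($D/\rho_f$); stiffness
   ($c_1 c_2 \beta \xi_0^{\beta-1}$) sets the propagation speed
   $v_\beta$. The restoring term $\omega_D^2$ arises because outflow grows
   with pressure, hence with volume: it is what lets a sustained flow
   increase settle at the Grubb steady state $\delta v = \delta f / \beta$
   instead of growing without bound, so we retain it rather than dropping
   it from the reduced equation.

3. **dHb balance.** Hemoglobin arrives fully oxygenated with inflowing
   blood ($\psi$ mmol per kg of blood), is converted to dHb as oxygen
   passes to tissue at rate $\eta$, and leaves with venous outflow. In
   fractional variables,
   $$\dot q = \Big(\frac{\eta}{E_0} - \frac{\beta-1}{\tau}
     + \frac{V_0 \beta}{\tau}\Big) v + V_0 \dot v - \frac{V_0}{\tau} f
     - \Big(\eta + \frac{1}{\tau}\Big) q,$$
   where $E_0$ is the resting oxygen extraction fraction. The resting
   balance between conversion and outflow ties it to the other parameters:
   $\psi \xi_0 / Q_0 = 1/E_0$ and $\eta = E_0 / (\tau (1 - E_0))$. Flow
   washout
   (the $-(\beta-1)/\tau\,v$ and $-V_0 f/\tau$ terms) initially depresses
   dHb; oxygen conversion then produces the delayed rise during vessel
   relaxation.

4. **BOLD observation.** The standard semi-empirical relation
   $y = V_0 [k_1(1-q) + k_2(1-q/v) + k_3(1-v)]$, linearized:
   $y = 100\,V_0[(k_2-k_3)\,v - (k_1+k_2)\,q]$ percent signal change, with
   3 T coefficients $k_1 = 7 E_0$, $k_2 = 2$, $k_3 = 2E_0 - 0.2$ and
   resting venous volume fraction $V_0 = 0.03$.

All four stages are composed in the Fourier domain into transfer functions
$T_{Lz}(k, \omega)$ for $L \in \{F, \xi, Q, y\}$
(`assemble_transfer_functions()`); responses to arbitrary drives are
inverse transforms of $T_{yz} \hat z$ (`simulate_response()`). The forward
transform kernel is $e^{-i(kx + \omega t)}$ everywhere.

## The reduced parameterization and the distortionless choice

Two parameters govern the spatial physics: the wave speed $v_\beta$ (mm/s)
and the damping rate $\Gamma$ (s$^{-1}$). `wave_params(v_beta, Gamma)`
parameterizes simulations directly in this space. One degree of freedom
remains open at this level: how $2\Gamma$ splits between outflow and
viscosity, which sets $\omega_D$. We default to the **balanced split**
$\beta/\tau = D/\rho_f = \Gamma$, i.e. $\omega_D = \Gamma$, for two
reasons:

* Substituting $v = e^{-\Gamma t} w$ turns the wave operator into the pure
  wave equation $\ddot w = v_\beta^2 \nabla^2 w$: the medium is
  *distortionless* (the analogue of the Heaviside condition for lossy
  transmission lines). Every frequency propagates at exactly $v_\beta$ and
  attenuates spatially at exactly $K = \Gamma / v_\beta$, so a disturbance
  travels as a delayed, exponentially attenuated replica of itself. This
  is precisely the empirical signature the estimation pipeline measures
  (straight phase fronts; log-linear decay in $x$ and $t$ with
  $|\Gamma_t| = K v$), and it makes wave speed and damping identifiable
  from data without deconvolving the temporal stages.
* It keeps the Grubb steady state exact at all damping levels.

With an unequal split ($\omega_D < \Gamma$, available via the `omega_D`
argument) the medium becomes weakly dispersive; the estimators then carry
a small bias that grows with the asymmetry.

For full physiological parameter sets (`hemo_params()`), $\Gamma$,
$v_\beta$ and $\omega_D$ are whatever the physiology implies;
`derive_reduced_params()` reports them, and the identity
$2\Gamma = \beta/\tau + D/\rho_f$ holds exactly by construction.

The drive gain $a_F$ is a calibration constant: by default it is chosen
(`calibrate_gain()`) so that the central peak of the simulated response to
the standard line stimulus is 0.4% signal change, the amplitude scale of
the flat-map responses the paradigm elicits. Being a pure scale factor in
a linear model it affects no speed, damping or width estimate.

## Numerical solvers

The spectral solver evaluates $T_{yz}$ on the FFT lattice and inverse
transforms. Two numerical choices matter:

* **Padding.** The FFT domain is periodic; `pad_halfwidth()` sizes the
  spatial domain so the steady-state decay $e^{-Kx}$ falls below $e^{-7}$
  before the boundary, bounding wrap-around at the $10^{-3}$ level.
* **Nyquist bins.** On even-length grids the shared Nyquist bin is forced
  real, which an exactly Hermitian filter requires; and a bare grid delta
  excites Nyquist-level ringing (about 0.5% of peak, acausal by
  construction of the truncated spectrum), so `compute_sthrf()` uses a
  grid-scale Gaussian of unit integral as its default impulse.

`time_domain_oracle()` is an independent cross-check: an explicit
fourth-order finite-difference discretization of the same linear system,
integrated with classical Runge--Kutta on an internally refined grid
(default 4x in space, Courant number 0.3) and restricted back to the
requested grid. Spectral and time-domain solutions agree to better than
$10^{-3}$ relative L2 on the grids used in the tests; the oracle refuses
grids that violate the wave stability contract $dt \le dx / v_\beta$.

## The synthetic experiment

`make_flatmap_dataset()` emulates the V1 line-stimulus experiment: the
neural drive is a Gaussian line source (cross-sectional SD 1 mm) along a
centerline on the flat map, switched on for 8 s and off for 12.25 s over
8 blocks, each block onset delayed by a further 250 ms (the onset
dephasing that yields an effective 250 ms sampling in the emulated
acquisition), after a 14 s lead-in. The simulated BOLD field is resampled
to the flat-map acquisition pitch (0.75 mm, 0.25 s). For a straight
centerline the 2-D map is constructed from the 1-D cross-section by exact
translational symmetry; curved (polynomial) centerlines trigger a full
2-D spectral run.

Noise is additive and voxelwise: AR(1)-filtered Gaussian innovations
(innovation SD chosen so the stationary SD is 0.1% signal at the default
AR coefficient 0.3) plus a slow sinusoidal drift of amplitude 0.05%
(random frequency 0.003--0.008 Hz and phase per voxel). With the 0.4%
calibrated response this gives a peak SNR of about 4 before any
averaging, consistent with the visibly smooth but noisy single-voxel
traces such experiments produce. The generator records its seed and full
ground truth in the dataset (and in the JSON sidecar written by
`write_flatmap()`), and regenerates bit-identically from them.

What the generator does *not* emulate: scanner physics (distortion,
motion, spin history), cortical folding and surface-reconstruction error,
physiological (cardiac/respiratory) structured noise, and any nonlinearity
of the response at large amplitudes. Passing recovery tests on these data
therefore demonstrates that the pipeline measures the linear model's waves
correctly at realistic SNR, not that every property of real scans is
handled.

## The analysis pipeline

`recover_parameters()` composes the empirical procedure:

1. **Filtering.** Every voxel time series is low-pass filtered below
   0.1 Hz with a third-order Butterworth filter applied forward and
   backward. Zero phase is essential: the phase-front timing *is* the
   measurement, and a causal one-pass filter would delay it. The filter
   reflect-pads the series so the passes start settled.
2. **Masking.** Voxels responding to the stimulus are found by normalized
   Fourier power at the analysis frequency (threshold 0.40) and by
   magnitude coherence with a reference time course -- the stimulus
   envelope convolved with a canonical double-gamma HRF -- computed from
   segment-averaged cross-spectra (three segments per block, threshold
   0.4). Coherence, not raw power, drives the centerline mask because it
   is phase-locked to the paradigm.
3. **Centerline.** A polynomial `x = f(y)` is fitted to the masked voxels
   (amplitude-weighted, anchored to voxels reaching half the peak
   response), with the order selected by
   $\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2(\mathrm{order} + 2)$ and a
   tie-break: orders within $\Delta\mathrm{AIC} < 2$ of the minimum
   resolve to the smallest order. The tie-break formalizes the manual
   preference for the simplest adequate centerline when the criterion is
   nearly flat. Exactly polynomial data leave only rounding noise in the
   residual, so the RSS is floored at that level before taking logs.
4. **Isoeccentric averaging.** Each voxel is assigned its signed
   perpendicular distance to the centerline (positive toward the foveal
   side by convention); responses are binned at the voxel pitch out to
   10 mm and averaged per $(x, t)$. Empty bins are missing, never zero.
5. **Phase.** The averaged, stimulus-locked epoch (one block period,
   averaged over blocks) is demeaned per position and the analytic signal
   taken along time; its argument is the instantaneous phase, its modulus
   the envelope. Phase is masked below 10% of the peak envelope.
6. **Fronts.** The reference phase is read at the temporal peak of the
   central response; for each position beyond the 1 mm exclusion radius
   (the local, non-propagating core) the front time is the
   unwrapped-phase crossing nearest in continuation from the previous
   position. Fronts extend to where the envelope falls below 10% of the
   central peak, relaxed down to an absolute floor of 2% when fewer than
   6 points would survive; a side with fewer than 4 usable points or a
   non-advancing chain is flagged "no detectable propagation" rather than
   fitted.
7. **Fits.** Ordinary least squares of front time on distance gives the
   speed ($v = 1/\mathrm{slope}$; $t$ is regressed on $x$ because distance
   is the controlled variable along the front); log-linear fits of front
   amplitude on time and on distance give the signed temporal decay
   $\Gamma_t$ and the spatial decay $K$. All three regressions run on one
   common *linear portion* of the front: innermost points are dropped
   (at most down to 4) while removing the innermost point changes a fitted
   slope by more than 2%. This restriction implements the usual practice
   of fitting the straight part of a log-linear plot; physically, the
   innermost 2--3 mm are contaminated by the 1 mm Gaussian width of the
   neural source, which flattens both the timing and the amplitude
   profiles there. Regression standard errors propagate to 1-sd
   uncertainties, and the internal consistency $|\Gamma_t| = K v$ is
   checked and flagged beyond 3 sd.
8. **Width.** The FWHM of the spatial profile of the response amplitude at
   the analysis frequency, interpolated at the half-maximum crossings; a
   multi-peaked profile yields the widest contiguous span plus a flag.

One frequency detail: the block repetition period is 20.5 s (8 + 12.25 s
plus the 0.25 s dephasing step), so the fundamental lies at 0.049 Hz. The
pipeline analyzes at the empirically detected peak-power bin rather than
assuming a nominal value; on the synthetic paradigm that is the
fundamental, while real acquisitions folded to an effective cycle can peak
at a harmonic. The detected bin is recorded in every result.

## Validation and problem sizes

The test suite validates, among other things: the dispersion relation
$\omega = -i\Gamma \pm \sqrt{v_\beta^2 k^2 - \Gamma^2}$ against its closed
form; spectral-vs-finite-difference agreement (relative L2 below
$10^{-3}$ on 32x128 and 64x256 grids); exact recovery of speed and zero
decay from a pure traveling sinusoid; and full-pipeline parameter recovery
on synthetic flat maps. Noiseless recovery errors are a few percent across
the detectable regime ($v_\beta$ 1.5--6 mm/s, $\Gamma$ 0.4--1.2 s$^{-1}$),
and with the default noise the median recovery error over 20 seeds per
grid point stays well under 20%. Recovery runs use a 12 mm strip along the
line (17 rows) with the full 8-block session, which keeps a complete
simulate-analyze cycle around a second; the residual few-percent biases
shrink further with longer fronts (wider `x_max`) and finer simulation
steps.

Two caveats worth knowing:

* With very strong damping the propagating range shrinks toward the
  source width and the front carries few points; estimates there lean on
  the relaxed amplitude floor and are the least accurate (still within
  10% noiseless at $v_\beta = 1.5$, $\Gamma = 1.2$).
* The consistency identity $|\Gamma_t| = K v$ is exact only when all
  three fits share the same points, which is why the pipeline trims them
  jointly.

## Worked example

```{r example, eval = FALSE}
library(hemowave)

# simulate a subject with foveal-side physiology and recover it
ds <- make_flatmap_dataset(wave_params(2.3, 0.86), noise = no_noise())
est <- recover_parameters(ds)
est
#> <wave_estimates> analysis frequency 0.0489 Hz
#>   F: v = 2.35 +/- 0.03 mm/s, Gamma_t = -0.898 +/- 0.018 1/s, K = 0.382 +/- 0.004 1/mm (n = 6)
#>   P: v = 2.35 +/- 0.03 mm/s, Gamma_t = -0.898 +/- 0.018 1/s, K = 0.382 +/- 0.004 1/mm (n = 6)
#>   FWHM = 4.25 mm
#>   truth: v = 2.30, Gamma = 0.86; rel. deltas F: v +2.2%, Gamma +4.4%, K +2.2% | ...
```

The symmetric simulation recovers the same parameters on both sides; on
real data the foveal and peripheral sides differ and are reported
separately.
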
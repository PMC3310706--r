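# hemowave

Spatiotemporal hemodynamic response modelling and BOLD wave analysis.

High-resolution fMRI resolves structure below the spatial scale of the
hemodynamic response itself, so the common assumption that each voxel's
BOLD signal is an independent temporal convolution of local neural
activity breaks down. `hemowave` is for researchers who want to model --
and measure -- the spatial side of the hemodynamic response: it implements
a linearized poroelastic model of cortical hemodynamics in which vessels
are pores in elastic cortical tissue, and which predicts that a localized
neural event launches **damped traveling waves** of blood volume and BOLD
signal across the cortical sheet.

## The model in brief

Neural activity drives arterial inflow through a damped oscillator
(signal decay rate κ, elimination constant γ). Mass and momentum
conservation in the poroelastic medium, with the vessel constitutive law
P ∝ ξ^β (β the reciprocal Grubb exponent), linearize to a damped wave
equation for the fractional blood-volume perturbation v:

    ∂²v/∂t² + 2Γ ∂v/∂t + ω_D² v − v_β² ∇²v = (1/τ)(∂f/∂t + (D/ρ_f) f)

with damping 2Γ = β/τ + D/ρ_f (venous outflow + blood viscosity),
propagation speed v_β² = c₁c₂β ξ₀^(β−1) (vascular stiffness), and
dispersion ω(k) = −iΓ ± sqrt(v_β²k² − Γ²). A dHb balance (oxygen
transfer rate η) and the semi-empirical BOLD observation equation
(V₀, k₁, k₂, k₃) complete the chain from neural drive z to percent
signal change y. Two measurable parameters characterize the waves: the
speed v_β (mm/s) and the damping rate Γ (1/s), with spatial decay
K = Γ/v_β (1/mm).

The package provides:

* a spectral solver for the spatiotemporal hemodynamic response function
  (stHRF) and responses to arbitrary drives, with a finite-difference
  time-domain oracle for cross-validation;
* a synthetic flat-map fMRI generator emulating a V1 line-stimulus
  block-design experiment (Gaussian line source of σ = 1 mm; 8 s on /
  12.25 s off, 8 dephased blocks; 0.75 mm / 0.25 s sampling; AR(1) +
  drift noise), with full ground truth and seeded reproducibility;
* the empirical wave-analysis pipeline: zero-phase Butterworth filtering,
  response-power and stimulus-coherence masking, AIC-selected polynomial
  centerline fitting, isoeccentric averaging, Hilbert-transform phase
  fronts, and regression estimators for v, Γ, K and response FWHM;
* a command-line interface (`inst/cli/hemowave`) with `simulate`,
  `sweep`, `make-data`, `analyze` and `recover` commands, YAML
  configuration and JSON run reports.

## Worked example

Simulate a flat-map experiment with foveal-side physiology
(v_β = 2.3 mm/s, Γ = 0.86 s⁻¹) and recover the wave parameters:

```r
library(hemowave)

ds <- make_flatmap_dataset(wave_params(2.3, 0.86), noise = no_noise())
est <- recover_parameters(ds)
est
#> <wave_estimates> analysis frequency 0.0489 Hz
#>   F: v = 2.35 +/- 0.03 mm/s, Gamma_t = -0.898 +/- 0.018 1/s, K = 0.382 +/- 0.004 1/mm (n = 6)
#>   P: v = 2.35 +/- 0.03 mm/s, Gamma_t = -0.898 +/- 0.018 1/s, K = 0.382 +/- 0.004 1/mm (n = 6)
#>   FWHM = 4.25 mm
#>   truth: v = 2.30, Gamma = 0.86; rel. deltas F: v +2.2%, Gamma +4.4%, K +2.2% | ...
```

Reading the output: the phase fronts on the foveal (F, x > 0) and
peripheral (P, x < 0) sides advance at 2.35 mm/s (truth 2.3); the BOLD
amplitude along the front decays at 0.898 s⁻¹ in time (truth Γ = 0.86)
and 0.382 mm⁻¹ in space (truth Γ/v = 0.374); the response envelope is
4.25 mm wide at half maximum. Uncertainties are 1 sd from the regression
fits; `n` is the number of front points in the fitted linear portion.

A quick look at how speed and damping shape the response:

```r
parameter_sweep(c(1, 3, 6), c(0.4, 1.2))
#> <wave_sweep> propagation extent (mm) at threshold 0.1
#>  v_beta Gamma extent_mm ...
```

Extent grows with v_β and shrinks with Γ; in the strong-damping,
low-stiffness corner it collapses to the width of the neural input.

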
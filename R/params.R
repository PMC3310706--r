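#' Physiological parameter set for the poroelastic hemodynamic model
#'
#' Constructs the full parameter set of the linearized poroelastic model of
#' cortical hemodynamics: a flow-regulation stage (damped harmonic oscillator
#' in the arterial inflow), conservation of blood mass and momentum in a
#' porous elastic medium, a constitutive pressure--volume law parameterized by
#' the reciprocal Grubb exponent, deoxyhemoglobin (dHb) mass balance, and a
#' semi-empirical BOLD observation equation.
#'
#' Quantities that are tied to the resting state (`F0`, `xi0`, `c2`, `cP`,
#' `eta`, `Q0`) may be left `NULL`, in which case they are filled in from the
#' resting-state balance conditions:
#' \itemize{
#'   \item `xi0 = V0 * rho_f` (resting blood mass per unit tissue volume),
#'   \item `F0 = xi0 / tau` (inflow balances outflow at rest),
#'   \item `cP = F0 / P0` with `P0 = c2 * xi0^beta`,
#'   \item `eta = (E0 / (1 - E0)) / tau` and `Q0 = psi * xi0 * E0`, where
#'     `E0` is the resting oxygen extraction fraction.
#' }
#'
#' Alternatively, the reduced wave parameters may be prescribed directly via
#' `v_beta` and `Gamma`; the vascular stiffness `c2` and the damping split
#' (`tau`, `D`) are then back-solved so that the derived wave speed and
#' damping rate equal the requested values, using the balanced-dissipation
#' convention `beta/tau = D/rho_f = Gamma` (see
#' [derive_reduced_params()]).
#'
#' @param kappa Signal decay rate of the flow regulator (1/s).
#' @param gamma_f Flow-dependent elimination constant (1/s^2 in the
#'   oscillator equation; conventionally quoted in 1/s).
#' @param F0 Resting inflow, mass-normalized (kg m^-3 s^-1); derived if `NULL`.
#' @param rho_f Density of blood (kg m^-3).
#' @param xi0 Resting blood mass per unit tissue volume (kg m^-3); derived if
#'   `NULL`.
#' @param cP Venous outflow proportionality constant; derived if `NULL`.
#' @param c1 Pressure-gradient coupling constant (dimensionless).
#' @param c2 Constitutive proportionality constant in `P = c2 * xi^beta`;
#'   derived from `v_beta` if `NULL`.
#' @param D Viscous damping parameter (kg m^-3 s^-1); derived from `Gamma` if
#'   `NULL`.
#' @param beta Reciprocal Grubb exponent (dimensionless, >= 1). The default
#'   corresponds to the Grubb exponent 0.38.
#' @param tau Mean blood transit time through the voxel vasculature (s);
#'   derived from `Gamma` if `NULL`.
#' @param psi Hemoglobin content per unit blood mass (mmol kg^-1).
#' @param eta Rate at which oxygen passes from oxygenated hemoglobin to
#'   tissue (1/s); derived from `E0` if `NULL`.
#' @param V0 Resting blood volume fraction, in (0, 1).
#' @param Q0 Resting dHb content (mmol m^-3 tissue); derived if `NULL`.
#' @param k1,k2,k3 Acquisition-dependent BOLD coefficients (3 T defaults).
#' @param E0 Resting oxygen extraction fraction, used only to derive `eta`,
#'   `Q0` and the default `k1`, `k3`.
#' @param v_beta Optional target wave propagation speed (mm/s).
#' @param Gamma Optional target wave damping rate (1/s).
#'
#' @return An object of class `hemo_params` (a named list with the fields
#'   above, all filled in).
#' @seealso [derive_reduced_params()], [wave_params()]
#' @export
#' @examples
#' p <- hemo_params()
#' derive_reduced_params(p)
hemo_params <- function(kappa = 0.65, gamma_f = 0.41,
                        F0 = NULL, rho_f = 1062, xi0 = NULL, cP = NULL,
                        c1 = 1, c2 = NULL, D = NULL,
                        beta = 1 / 0.38, tau = NULL,
                        psi = 2.3, eta = NULL,
                        V0 = 0.03, Q0 = NULL,
                        k1 = 7 * E0, k2 = 2, k3 = 2 * E0 - 0.2,
                        E0 = 0.35,
                        v_beta = NULL, Gamma = NULL) {
  if (is.null(Gamma) && is.null(tau)) Gamma <- 0.8
  if (is.null(tau)) tau <- beta / Gamma          # balanced dissipation
  if (is.null(D)) {
    D <- if (!is.null(Gamma)) (2 * Gamma - beta / tau) * rho_f else (beta / tau) * rho_f
  }
  if (is.null(xi0)) xi0 <- V0 * rho_f
  if (is.null(c2)) {
    v_target <- if (!is.null(v_beta)) v_beta else 3
    c2 <- v_target^2 / (c1 * beta * xi0^(beta - 1))
  }
  if (is.null(F0)) F0 <- xi0 / tau
  if (is.null(cP)) cP <- F0 / (c2 * xi0^beta)
  if (is.null(eta)) eta <- (E0 / (1 - E0)) / tau
  if (is.null(Q0)) Q0 <- psi * xi0 * E0
  p <- structure(list(kappa = kappa, gamma_f = gamma_f, F0 = F0,
                      rho_f = rho_f, xi0 = xi0, cP = cP, c1 = c1, c2 = c2,
                      D = D, beta = beta, tau = tau, psi = psi, eta = eta,
                      V0 = V0, Q0 = Q0, k1 = k1, k2 = k2, k3 = k3),
                 class = "hemo_params")
  validate_hemo_params(p)
  p
}

validate_hemo_params <- function(p) {
  pos <- c("kappa", "gamma_f", "F0", "rho_f", "xi0", "cP", "c1", "c2",
           "beta", "tau", "psi", "eta", "Q0", "k1", "k2", "k3")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop("hemo_params: '", nm, "' must be a single positive finite number",
           call. = FALSE)
  }
  if (p$D < 0) stop("hemo_params: 'D' must be non-negative", call. = FALSE)
  if (p$beta < 1) stop("hemo_params: 'beta' must be >= 1", call. = FALSE)
  if (p$V0 <= 0 || p$V0 >= 1)
    stop("hemo_params: 'V0' must lie in (0, 1)", call. = FALSE)
  invisible(p)
}

#' Reduced wave parameters
#'
#' The linearized model collapses, for the blood-mass (volume) field, to a
#' damped wave equation characterized by a propagation speed `v_beta` and a
#' damping rate `Gamma`. `wave_params()` constructs this reduced
#' parameterization directly, which is the natural space in which to simulate
#' and in which the empirical estimators report.
#'
#' The restoring rate `omega_D` (the decay rate of a sustained spatially
#' uniform volume perturbation through venous outflow acting against vessel
#' elasticity) defaults to `Gamma`. That choice splits the dissipation
#' equally between blood viscosity and boundary outflow and makes the medium
#' distortionless: every temporal frequency propagates at `v_beta` and decays
#' spatially at rate `Gamma / v_beta`, so a disturbance travels as an
#' attenuated, delayed replica of itself. `omega_D <= Gamma` is required;
#' smaller values shift dissipation toward viscosity (or outflow) and make
#' the medium weakly dispersive.
#'
#' @param v_beta Wave propagation speed (mm/s), > 0.
#' @param Gamma Damping rate (1/s), > 0.
#' @param a_F Drive gain coupling flow to the wave equation. `NA` (default)
#'   means "calibrate on use" so that the simulated central response to the
#'   standard line stimulus has a peak of about 0.4% signal change; see
#'   [calibrate_gain()].
#' @param omega_D Restoring rate (1/s) in `[0, Gamma]`; default `Gamma`.
#' @return An object of class `wave_params`.
#' @export
#' @examples
#' wave_params(3, 0.8)
wave_params <- function(v_beta, Gamma, a_F = NA_real_, omega_D = Gamma) {
  if (!is.numeric(v_beta) || length(v_beta) != 1 || !is.finite(v_beta) ||
      v_beta <= 0)
    stop("wave_params: 'v_beta' must be a single positive number", call. = FALSE)
  if (!is.numeric(Gamma) || length(Gamma) != 1 || !is.finite(Gamma) ||
      Gamma <= 0)
    stop("wave_params: 'Gamma' must be a single positive number", call. = FALSE)
  if (omega_D < 0 || omega_D > Gamma + 1e-12)
    stop("wave_params: 'omega_D' must lie in [0, Gamma]", call. = FALSE)
  structure(list(v_beta = v_beta, Gamma = Gamma, a_F = a_F,
                 omega_D = omega_D),
            class = "wave_params")
}

#' Derive the reduced wave parameters from the physiological set
#'
#' Linearizing the mass-conservation, momentum and constitutive equations
#' about the resting state and eliminating velocity and pressure yields a
#' damped wave equation for the blood-mass perturbation, with
#' `2 * Gamma = beta / tau + D / rho_f` (dissipation through boundary outflow
#' plus blood viscosity), squared propagation speed
#' `v_beta^2 = c1 * c2 * beta * xi0^(beta - 1)` (vascular stiffness), and a
#' restoring rate `omega_D^2 = (beta / tau) * (D / rho_f)`.
#'
#' @param p A [hemo_params()] object.
#' @return A [wave_params()] object (with `a_F = NA`, i.e. calibrated on use).
#' @export
derive_reduced_params <- function(p) {
  stopifnot(inherits(p, "hemo_params"))
  validate_hemo_params(p)
  Gamma <- (p$beta / p$tau + p$D / p$rho_f) / 2
  v2 <- p$c1 * p$c2 * p$beta * p$xi0^(p$beta - 1)
  if (!is.finite(Gamma) || Gamma <= 0)
    stop("derive_reduced_params: derived Gamma is not positive", call. = FALSE)
  if (!is.finite(v2) || v2 <= 0)
    stop("derive_reduced_params: derived v_beta is not positive", call. = FALSE)
  omega_D <- sqrt((p$beta / p$tau) * (p$D / p$rho_f))
  wave_params(v_beta = sqrt(v2), Gamma = Gamma, a_F = NA_real_,
              omega_D = omega_D)
}

#' @export
print.hemo_params <- function(x, ...) {
  cat("<hemo_params>\n")
  for (nm in names(x)) cat(sprintf("  %-8s %.6g\n", nm, x[[nm]]))
  r <- derive_reduced_params(x)
  cat(sprintf("  derived: v_beta = %.3g mm/s, Gamma = %.3g 1/s, omega_D = %.3g 1/s\n",
              r$v_beta, r$Gamma, r$omega_D))
  invisible(x)
}

#' @export
print.wave_params <- function(x, ...) {
  cat(sprintf("<wave_params> v_beta = %.3g mm/s, Gamma = %.3g 1/s, omega_D = %.3g 1/s, a_F = %s\n",
              x$v_beta, x$Gamma, x$omega_D,
              if (is.na(x$a_F)) "auto" else format(x$a_F, digits = 3)))
  invisible(x)
}

# Constants of the full transfer-function chain, for either parameter class.
# For wave_params the temporal stages use the canonical physiological
# defaults, with the transit time tied to Gamma through the balanced split.
chain_constants <- function(pars) {
  if (inherits(pars, "hemo_params")) {
    validate_hemo_params(pars)
    r <- derive_reduced_params(pars)
    E0 <- pars$Q0 / (pars$psi * pars$xi0)
    list(kappa = pars$kappa, gamma_f = pars$gamma_f,
         beta = pars$beta, tau = pars$tau, eta = pars$eta,
         E0 = E0, V0 = pars$V0,
         k1 = pars$k1, k2 = pars$k2, k3 = pars$k3,
         v = r$v_beta, Gamma = r$Gamma, omega_D = r$omega_D,
         drive_d = pars$D / pars$rho_f, a_F = NA_real_)
  } else if (inherits(pars, "wave_params")) {
    beta <- 1 / 0.38
    Gamma <- pars$Gamma
    # split 2*Gamma = beta/tau + d with (beta/tau)*d = omega_D^2,
    # outflow-dominant root
    disc <- sqrt(max(Gamma^2 - pars$omega_D^2, 0))
    b_t <- Gamma + disc          # beta / tau
    d <- Gamma - disc            # D / rho_f
    tau <- beta / b_t
    E0 <- 0.35
    list(kappa = 0.65, gamma_f = 0.41,
         beta = beta, tau = tau, eta = (E0 / (1 - E0)) / tau,
         E0 = E0, V0 = 0.03,
         k1 = 7 * E0, k2 = 2, k3 = 2 * E0 - 0.2,
         v = pars$v_beta, Gamma = Gamma, omega_D = pars$omega_D,
         drive_d = d, a_F = pars$a_F)
  } else {
    stop("expected a 'hemo_params' or 'wave_params' object", call. = FALSE)
  }
}
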
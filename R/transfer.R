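#' Flow-stage transfer function
#'
#' Frequency response of the arterial flow regulator, a damped harmonic
#' oscillator in the fractional inflow driven by neural activity,
#' parameterized by the signal decay rate `kappa` and the flow-dependent
#' elimination constant `gamma_f`. The gain is normalized to 1 at zero
#' frequency so that the drive gain `a_F` alone sets response amplitude.
#'
#' The Fourier convention throughout the package is a forward transform with
#' kernel `exp(-i (k x + omega t))`; a time derivative therefore maps to
#' multiplication by `i * omega`.
#'
#' @param omega Temporal angular frequency (rad/s), any numeric vector.
#' @param p A [hemo_params()] or [wave_params()] object.
#' @return Complex gain, same length as `omega`.
#' @export
#' @examples
#' flow_transfer(0, hemo_params())          # exactly 1
flow_transfer <- function(omega, p) {
  cc <- chain_constants(p)
  s <- 1i * omega
  cc$gamma_f / (cc$gamma_f + s^2 + cc$kappa * s)
}

#' Dispersion relation of the hemodynamic wave equation
#'
#' Complex temporal roots `omega(k)` of the damped wave equation for modes
#' proportional to `exp(i (k x - omega t))`:
#' `omega^2 + 2i * Gamma * omega - v_beta^2 * k^2 = 0`, i.e.
#' `omega = -i * Gamma +/- sqrt(v_beta^2 * k^2 - Gamma^2)`.
#' Both roots have non-positive imaginary part for `Gamma > 0` (all modes
#' damped); the phase speed `|Re omega| / k` increases with `k` and
#' approaches `v_beta`.
#'
#' @param k Spatial angular frequency (rad/mm), numeric vector.
#' @param r A [wave_params()] object (or [hemo_params()], reduced first).
#' @return A complex matrix with `length(k)` rows and columns `plus`,
#'   `minus`.
#' @export
#' @examples
#' dispersion(0, wave_params(3, 0.8))   # roots 0 and -2i*Gamma
dispersion <- function(k, r) {
  if (inherits(r, "hemo_params")) r <- derive_reduced_params(r)
  stopifnot(inherits(r, "wave_params"))
  disc <- sqrt(as.complex(r$v_beta^2 * k^2 - r$Gamma^2))
  cbind(plus = -1i * r$Gamma + disc, minus = -1i * r$Gamma - disc)
}

# Wave-stage gain: fractional blood-mass (volume) response per unit
# fractional flow, at (k2 = |k|^2, s = i*omega).  Includes the restoring
# rate omega_D from outflow acting against vessel elasticity; the drive is
# (1/tau) * (d/dt + drive_d) applied to fractional flow.
wave_stage <- function(s, k2, cc) {
  den <- s^2 + 2 * cc$Gamma * s + cc$omega_D^2 + cc$v^2 * k2
  out <- (1 / cc$tau) * (s + cc$drive_d) / den
  if (cc$omega_D == 0) {
    # pure telegraph limit: removable 0/0 at the DC bin
    zero <- which(Mod(den) == 0)
    out[zero] <- 1 / (cc$tau * 2 * cc$Gamma)
  }
  out
}

# dHb-stage coupling coefficients (fractional variables).  The dHb balance
# linearizes to
#   dq/dt = [eta/E0 - (beta-1)/tau + V0*beta/tau] v + V0 * dv/dt
#           - (V0/tau) f - (eta + 1/tau) q
# where v is fractional blood mass, f fractional flow, q fractional dHb.
dhb_coeffs <- function(s, cc) {
  inv_tau <- if (is.finite(cc$tau)) 1 / cc$tau else 0
  list(cv = cc$eta / cc$E0 - (cc$beta - 1) * inv_tau +
         cc$V0 * cc$beta * inv_tau + cc$V0 * s,
       cf = -cc$V0 * inv_tau,
       den = s + cc$eta + inv_tau)
}

#' dHb-stage transfer function
#'
#' Linearized first-order dynamics of the fractional deoxyhemoglobin
#' perturbation: oxygen conversion from the oxygenated pool (source
#' `(psi*xi - Q)*eta`), removal by venous outflow, and advective dilution by
#' fresh inflow. By default returns the gain from the fractional blood-mass
#' (volume) perturbation to fractional dHb; `input = "flow"` returns the
#' direct dilution gain from fractional flow, and `input = "neural"` the
#' full composed gain from the neural drive.
#'
#' The single pole sits at `-(eta + 1/tau)` (rate `eta` when outflow is
#' disabled with `tau = Inf`): dHb perturbations relax exponentially at the
#' oxygen-transfer rate plus the outflow turnover rate.
#'
#' @param k Spatial angular frequency (rad/mm); only the composed
#'   `"neural"` gain depends on it.
#' @param omega Temporal angular frequency (rad/s).
#' @param p Parameter object. For `tau = Inf` (outflow disabled) pass a
#'   `hemo_params`-like list via `tau_override`.
#' @param input Which perturbation the gain refers to.
#' @param tau_override Optional transit time overriding the parameter set
#'   (use `Inf` to disable outflow).
#' @return Complex gain array of dimension `length(k) x length(omega)`
#'   (dropped to a vector when either has length 1).
#' @export
dhb_transfer <- function(k, omega, p, input = c("xi", "flow", "neural"),
                         tau_override = NULL) {
  input <- match.arg(input)
  cc <- chain_constants(p)
  if (!is.null(tau_override)) cc$tau <- tau_override
  s <- 1i * outer(rep(1, length(k)), omega)
  co <- dhb_coeffs(s, cc)
  g <- switch(input,
    xi = co$cv / co$den,
    flow = co$cf / co$den,
    neural = {
      k2 <- outer(k^2, rep(1, length(omega)))
      wv <- wave_stage(s, k2, cc)
      fl <- cc$gamma_f / (cc$gamma_f + s^2 + cc$kappa * s)
      aF <- if (is.na(cc$a_F)) 1 else cc$a_F
      aF * fl * (co$cv * wv + co$cf) / co$den
    })
  drop(g)
}

#' Linearized BOLD observation equation
#'
#' Maps fractional perturbations of blood mass (volume) and dHb content to
#' percent BOLD signal change, by linearizing the semi-empirical relation
#' `y = V0 * (k1 (1 - q) + k2 (1 - q / v) + k3 (1 - v))` about rest:
#' `y = 100 * V0 * ((k2 - k3) * dv - (k1 + k2) * dq)`.
#'
#' @param xi_pert Fractional blood-mass perturbation: an [hw_field()]
#'   (quantity `"xi"`) or array.
#' @param q_pert Fractional dHb perturbation: an [hw_field()] (quantity
#'   `"Q"`) or array on the same grid.
#' @param p Parameter object.
#' @param grid Grid (required when passing bare arrays).
#' @return An [hw_field()] of quantity `"y"` in percent signal change.
#' @export
bold_signal <- function(xi_pert, q_pert, p, grid = NULL) {
  if (inherits(xi_pert, "hw_field")) grid <- xi_pert$grid
  if (is.null(grid) && inherits(q_pert, "hw_field")) grid <- q_pert$grid
  if (is.null(grid)) stop("bold_signal: no grid supplied", call. = FALSE)
  xv <- field_array(field_values(xi_pert), grid)
  qv <- field_array(field_values(q_pert), grid)
  cc <- chain_constants(p)
  y <- 100 * cc$V0 * ((cc$k2 - cc$k3) * xv - (cc$k1 + cc$k2) * qv)
  hw_field(y, grid, quantity = "y", units = "percent")
}

nyquist_real <- function(Tc, grid) {
  fix <- function(A, along, n) {
    if (n %% 2 != 0) return(A)
    i <- n / 2 + 1
    if (length(dim(A)) == 2) {
      if (along == 1) A[i, ] <- Re(A[i, ]) else A[, i] <- Re(A[, i])
    } else {
      if (along == 1) A[i, , ] <- Re(A[i, , ])
      else if (along == 2) A[, i, ] <- Re(A[, i, ])
      else A[, , i] <- Re(A[, , i])
    }
    A
  }
  nd <- length(dim(Tc))
  Tc <- fix(Tc, 1, grid$nx)
  if (nd == 3) Tc <- fix(Tc, 2, grid$ny)
  fix(Tc, nd, grid$nt)
}

# Full spectral transfer functions on a grid's (k, omega) lattice.
# Returns complex arrays shaped like the simulation spectrum.
build_transfer <- function(pars, grid, a_F = NULL) {
  cc <- chain_constants(pars)
  if (!is.null(a_F)) cc$a_F <- a_F
  if (cc$Gamma <= 0) stop("transfer functions require Gamma > 0 (undamped pole)",
                          call. = FALSE)
  om <- grid_omega(grid)
  kx <- grid_kx(grid)
  if (grid$ny == 1L) {
    s <- matrix(1i * om, grid$nx, grid$nt, byrow = TRUE)
    k2 <- matrix(kx^2, grid$nx, grid$nt)
  } else {
    s <- aperm(array(1i * om, c(grid$nt, grid$nx, grid$ny)), c(2, 3, 1))
    k2 <- outer(kx^2, rep(1, grid$ny)) + outer(rep(1, grid$nx), grid_ky(grid)^2)
    k2 <- array(k2, c(grid$nx, grid$ny, grid$nt))
  }
  aF <- if (is.na(cc$a_F)) 1 else cc$a_F
  T_F <- aF * cc$gamma_f / (cc$gamma_f + s^2 + cc$kappa * s)   # flow <- z
  W <- wave_stage(s, k2, cc)                                   # xi <- flow
  co <- dhb_coeffs(s, cc)
  T_xi <- W * T_F
  T_Q <- (co$cv * W + co$cf) / co$den * T_F
  T_y <- 100 * cc$V0 * ((cc$k2 - cc$k3) * T_xi - (cc$k1 + cc$k2) * T_Q)
  # Even-length FFT grids share one Nyquist bin between +f and -f; a filter
  # with a real impulse response must be real there.
  T_F <- nyquist_real(T_F, grid); T_xi <- nyquist_real(T_xi, grid)
  T_Q <- nyquist_real(T_Q, grid); T_y <- nyquist_real(T_y, grid)
  list(T_Fz = T_F, T_xiz = T_xi, T_Qz = T_Q, T_yz = T_y,
       omega = om, kx = kx, ky = if (grid$ny > 1L) grid_ky(grid) else NULL,
       cc = cc)
}

#' Assemble the spatiotemporal transfer-function set
#'
#' Composes the linearized stages -- flow regulation, damped blood-mass
#' wave, dHb balance and BOLD observation -- into the set of complex
#' spatiotemporal filters `T_Lz(k, omega)` for `L` in `{F, xi, Q, y}`,
#' evaluated on the grid's discrete frequency lattice (wrap-around FFT
#' ordering). The filters are Hermitian-symmetric,
#' `T(-k, -omega) = Conj(T(k, omega))`, so that responses to real drives
#' are real.
#'
#' @param pars A [hemo_params()] or [wave_params()] object.
#' @param grid An [st_grid()].
#' @return An object of class `transfer_set`: complex arrays `T_Fz`,
#'   `T_xiz`, `T_Qz`, `T_yz` plus the frequency grids `omega`, `kx` (and
#'   `ky` in 2-D).
#' @export
assemble_transfer_functions <- function(pars, grid) {
  tf <- build_transfer(pars, grid)
  structure(tf[c("T_Fz", "T_xiz", "T_Qz", "T_yz", "omega", "kx", "ky")],
            class = "transfer_set", grid = grid)
}

#' @export
print.transfer_set <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<transfer_set> %d x %d x %d (kx, ky, omega) complex filters: T_Fz, T_xiz, T_Qz, T_yz\n",
              g$nx, g$ny, g$nt))
  invisible(x)
}
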
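#' Stimulus specification for the line-source block paradigm
#'
#' Describes the neural drive used throughout: a Gaussian line source of
#' neural activity on the flat map (cross-sectional standard deviation
#' `sigma_x`) switched on and off in a block design. Defaults emulate the
#' V1 isoeccentric-ring paradigm: 8 s on, 12.25 s off, 8 blocks, with each
#' block's onset additionally delayed by `dephase_step` per block (onset
#' dephasing used to increase effective temporal sampling), preceded by a
#' `lead_in` rest.
#'
#' @param sigma_x Gaussian half-width of the line source (mm).
#' @param on_duration,off_duration Block on/off durations (s).
#' @param n_blocks Number of stimulus blocks.
#' @param dephase_step Onset dephasing per block (s).
#' @param lead_in Rest before the first block (s).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(sigma_x = 1, on_duration = 8, off_duration = 12.25,
                          n_blocks = 8, dephase_step = 0.25, lead_in = 14) {
  stopifnot(sigma_x > 0, on_duration > 0, off_duration > 0, n_blocks >= 1,
            dephase_step >= 0, lead_in >= 0)
  structure(list(sigma_x = sigma_x, on_duration = on_duration,
                 off_duration = off_duration, n_blocks = as.integer(n_blocks),
                 dephase_step = dephase_step, lead_in = lead_in),
            class = "stimulus_spec")
}

#' Block onset times
#'
#' Onset of block `b` (0-based) is
#' `lead_in + b * (on + off) + b * dephase_step`: successive onsets are
#' shifted by an extra `dephase_step` each block.
#'
#' @param spec A [stimulus_spec()].
#' @return Numeric vector of onset times (s).
#' @export
stimulus_onsets <- function(spec) {
  b <- 0:(spec$n_blocks - 1)
  spec$lead_in + b * (spec$on_duration + spec$off_duration) +
    b * spec$dephase_step
}

# effective repetition period including the dephasing step
stimulus_period <- function(spec)
  spec$on_duration + spec$off_duration + spec$dephase_step

# on/off envelope sampled at times t
stimulus_envelope <- function(spec, t) {
  env <- numeric(length(t))
  for (on in stimulus_onsets(spec))
    env[t >= on & t < on + spec$on_duration] <- 1
  env
}

#' Gaussian line-source neural drive
#'
#' Builds the neural drive field `z(r, t)`: a Gaussian cross-section of
#' standard deviation `sigma_x` about a centerline, multiplied by the block
#' time course with per-block onset dephasing. On a 1-D grid the centerline
#' is a single offset; on a 2-D grid it is a polynomial `x = f(y)`
#' (coefficients in increasing order).
#'
#' @param spec A [stimulus_spec()].
#' @param centerline Numeric: constant offset (1-D or straight 2-D line) or
#'   polynomial coefficients `c(c0, c1, ...)` for `x = f(y)`.
#' @param grid An [st_grid()].
#' @return An [hw_field()] of quantity `"z"`.
#' @export
line_stimulus <- function(spec, centerline, grid) {
  env <- stimulus_envelope(spec, grid$t)
  if (grid$ny == 1L) {
    if (length(centerline) != 1)
      stop("line_stimulus: 1-D grid takes a single centerline offset", call. = FALSE)
    if (centerline < min(grid$x) || centerline > max(grid$x))
      stop("line_stimulus: centerline lies outside the grid", call. = FALSE)
    gx <- exp(-(grid$x - centerline)^2 / (2 * spec$sigma_x^2))
    return(hw_field(outer(gx, env), grid, quantity = "z"))
  }
  xc <- polyval_asc(centerline, grid$y)
  if (any(xc < min(grid$x)) || any(xc > max(grid$x)))
    stop("line_stimulus: centerline exits the grid", call. = FALSE)
  d <- signed_curve_distance(grid$x, grid$y, centerline)
  gxy <- exp(-d^2 / (2 * spec$sigma_x^2))
  z <- array(0, c(grid$nx, grid$ny, grid$nt))
  for (it in seq_len(grid$nt)) if (env[it] > 0) z[, , it] <- gxy * env[it]
  hw_field(z, grid, quantity = "z")
}

# polynomial with ascending coefficients
polyval_asc <- function(coef, x) {
  out <- numeric(length(x))
  for (j in seq_along(coef)) out <- out + coef[j] * x^(j - 1)
  out
}

# signed perpendicular distance from each (x, y) node to the curve x = f(y);
# positive toward larger x.  Dense sampling of the curve.
signed_curve_distance <- function(xs, ys, coef, step = 0.05) {
  if (length(coef) == 1) return(outer(xs - coef, rep(1, length(ys))))
  yd <- seq(min(ys) - 5, max(ys) + 5, by = step)
  cx <- polyval_asc(coef, yd)
  d <- matrix(0, length(xs), length(ys))
  for (iy in seq_along(ys)) {
    for (ix in seq_along(xs)) {
      dd <- sqrt((xs[ix] - cx)^2 + (ys[iy] - yd)^2)
      d[ix, iy] <- min(dd) * sign(xs[ix] - polyval_asc(coef, ys[iy]))
    }
  }
  d
}
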
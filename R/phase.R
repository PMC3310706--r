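#' Instantaneous phase of the averaged response
#'
#' Computes, for every perpendicular distance `x`, the analytic signal of
#' the (demeaned) time series and from it the instantaneous phase
#' `phi(x, t)` and amplitude envelope `A(x, t)`. Phase is masked (set `NA`)
#' where the envelope falls below `floor_frac` of the overall peak
#' envelope, since phase is meaningless at noise level.
#'
#' The input is expected to be the stimulus-locked, low-pass-filtered
#' average `y(x, t)`; rows containing missing bins are masked.
#'
#' @param avg An `avg_response` from [isoeccentric_average()], or a numeric
#'   matrix (rows = positions) with `t` supplied.
#' @param t Time vector (s) when `avg` is a bare matrix.
#' @param x Position vector (mm) when `avg` is a bare matrix.
#' @param f0 Analysis frequency (Hz), recorded in the result.
#' @param floor_frac Amplitude floor as a fraction of the peak envelope.
#' @return An object of class `phase_field`: `phi` (radians, masked),
#'   `env`, `mask`, `x`, `t`, `f0`.
#' @export
analytic_phase <- function(avg, t = NULL, x = NULL, f0 = NULL,
                           floor_frac = 0.1) {
  if (inherits(avg, "avg_response")) {
    y <- avg$y; t <- avg$t; x <- avg$x
  } else y <- avg
  ok_row <- apply(is.finite(y), 1, all)
  phi <- env <- matrix(NA_real_, nrow(y), ncol(y))
  for (i in which(ok_row)) {
    a <- analytic_signal(y[i, ] - mean(y[i, ]))
    phi[i, ] <- Arg(a)
    env[i, ] <- Mod(a)
  }
  floor_amp <- floor_frac * max(env, na.rm = TRUE)
  mask <- is.finite(env) & env >= floor_amp
  phi_raw <- phi
  phi[!mask] <- NA_real_
  structure(list(phi = phi, env = env, mask = mask, x = x, t = t, f0 = f0,
                 floor_frac = floor_frac, phi_raw = phi_raw),
            class = "phase_field")
}

#' Extract phase fronts through the central peak
#'
#' The reference phase `phi0` is taken at the temporal peak of the central
#' (x ~ 0) response. For each position beyond the exclusion radius the
#' front time is the unwrapped-phase crossing of `phi0` nearest (in
#' continuation from the previous position) to the central peak time;
#' fronts are traced outward on each side, foveal (`F`, positive x) and
#' peripheral (`P`, negative x).
#'
#' Fronts are limited to positions whose envelope reaches `floor_frac`
#' (default 10%) of the central peak; when fewer than `min_points` survive
#' the floor is relaxed down to `hard_floor` to retain a minimum usable
#' front, short propagating ranges permitting. A side with no usable
#' crossing chain, or a non-monotone chain, is flagged
#' `"no detectable propagation"`.
#'
#' @param pf A [analytic_phase()] result.
#' @param x_min Exclusion radius (mm) around the local response, default 1.
#' @param x_max Maximum |x| considered (mm), default 10.
#' @param floor_frac Amplitude floor relative to the central peak.
#' @param min_points Minimum number of front points aimed for.
#' @param hard_floor Absolute lower amplitude bound (fraction of central
#'   peak) when relaxing the floor.
#' @return A list with elements `F` and `P`, each of class `wave_front`:
#'   `x` (absolute distance, mm), `t` (front time, s), `amplitude`
#'   (envelope at the front), `side`, `phi0`, `flag`.
#' @export
extract_phase_front <- function(pf, x_min = 1, x_max = 10, floor_frac = 0.1,
                                min_points = 6, hard_floor = 0.02) {
  i0 <- which.min(abs(pf$x))
  if (!any(is.finite(pf$env[i0, ])))
    stop("extract_phase_front: no central response", call. = FALSE)
  ipk <- which.max(pf$env[i0, ])
  A0 <- pf$env[i0, ipk]
  phi0 <- Arg(exp(1i * pf$phi[i0, ipk]))
  dt <- pf$t[2] - pf$t[1]
  one_side <- function(sgn) {
    sel <- which(sgn * pf$x > x_min & sgn * pf$x <= x_max)
    sel <- sel[order(abs(pf$x[sel]))]
    xs <- ts <- as_ <- numeric(0)
    tprev <- pf$t[ipk]
    for (i in sel) {
      # the analytic-signal phase is defined wherever the envelope is
      # positive; the display mask is not applied here, since the front's
      # own amplitude floor (below) governs which positions are kept
      ph <- if (!is.null(pf$phi_raw)) pf$phi_raw[i, ] else pf$phi[i, ]
      if (!all(is.finite(ph))) {
        valid <- is.finite(ph)
        if (sum(valid) < 4) next
        ph[!valid] <- stats::approx(pf$t[valid], ph[valid], xout = pf$t[!valid],
                                    rule = 2)$y
      }
      phu <- unwrap_phase(ph)
      tc <- phase_crossings(phu, phi0, pf$t)
      if (!length(tc)) next
      tb <- tc[which.min(abs(tc - tprev))]
      xs <- c(xs, abs(pf$x[i])); ts <- c(ts, tb)
      as_ <- c(as_, stats::approx(pf$t, pf$env[i, ], xout = tb)$y)
      tprev <- tb
    }
    keep <- is.finite(as_) & as_ > 0
    xs <- xs[keep]; ts <- ts[keep]; as_ <- as_[keep]
    above <- as_ >= floor_frac * A0
    if (sum(above) < min_points) {
      hard <- as_ >= hard_floor * A0
      cut <- which(cumsum(hard) <= min_points & hard)
      above <- seq_along(as_) %in% cut | above
    }
    xs <- xs[above]; ts <- ts[above]; as_ <- as_[above]
    flag <- NULL
    if (length(xs) < 4) flag <- "no detectable propagation"
    else if (stats::cor(xs, ts, method = "kendall") <= 0)
      flag <- "no detectable propagation"
    structure(list(x = xs, t = ts, amplitude = as_,
                   side = if (sgn > 0) "F" else "P",
                   phi0 = phi0, central_peak = A0, flag = flag),
              class = "wave_front")
  }
  list(F = one_side(+1), P = one_side(-1))
}

# all sub-sample crossing times of phi0 (mod 2*pi) in an unwrapped series
phase_crossings <- function(phu, phi0, t) {
  d <- phu - phi0
  out <- numeric(0)
  for (j in seq_len(length(t) - 1)) {
    m <- floor(d[j] / (2 * pi) + 0.5)
    for (mm in (m - 1):(m + 1)) {
      a <- d[j] - 2 * pi * mm; b <- d[j + 1] - 2 * pi * mm
      if (a == 0) out <- c(out, t[j])
      else if (a * b < 0) out <- c(out, t[j] + (t[j + 1] - t[j]) * a / (a - b))
    }
  }
  sort(unique(out))
}

#' @export
print.wave_front <- function(x, ...) {
  cat(sprintf("<wave_front %s> %d points, |x| in [%.2g, %.2g] mm%s\n", x$side,
              length(x$x), if (length(x$x)) min(x$x) else NA,
              if (length(x$x)) max(x$x) else NA,
              if (!is.null(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}
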
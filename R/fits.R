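# Restrict a front to the linear portion of a regression: drop the
# innermost point while its removal changes the fitted slope by more than
# `tol` (relative), keeping at least `nmin` points.  The innermost points
# sit closest to the local (source-width-dominated) region, where the
# log-amplitude and timing profiles flatten.
trim_linear_portion <- function(xs, ys, tol = 0.02, nmin = 4) {
  keep <- seq_along(xs)
  while (length(keep) > nmin) {
    s_all <- stats::coef(stats::lm(ys[keep] ~ xs[keep]))[2]
    s_out <- stats::coef(stats::lm(ys[keep[-1]] ~ xs[keep[-1]]))[2]
    if (is.finite(s_all) && is.finite(s_out) &&
        abs(s_out - s_all) > tol * abs(s_all)) keep <- keep[-1] else break
  }
  keep
}

#' Wave speed from a phase front
#'
#' Ordinary least squares of front time on absolute distance (distance is
#' the controlled variable on the front); the speed is the reciprocal
#' slope, with its standard deviation propagated from the slope standard
#' error. By default the fit is restricted to the linear portion of the
#' front (see the package vignette): the innermost points are dropped while
#' they curve the fit.
#'
#' @param front A `wave_front` from [extract_phase_front()].
#' @param trim Restrict to the linear portion (default TRUE).
#' @param trim_tol Relative slope-change tolerance for trimming.
#' @param keep Optional explicit point indices to fit (overrides `trim`).
#' @return A list of class `speed_fit`: `v` (mm/s), `sd`, `slope`,
#'   `slope_sd`, `r2`, `n`, `flag` (`"unphysical"` when the slope is not
#'   positive, or the front's own flag).
#' @export
fit_wave_speed <- function(front, trim = TRUE, trim_tol = 0.02, keep = NULL) {
  if (!is.null(front$flag))
    return(structure(list(v = NA_real_, sd = NA_real_, slope = NA_real_,
                          slope_sd = NA_real_, r2 = NA_real_, n = length(front$x),
                          flag = front$flag), class = "speed_fit"))
  if (length(front$x) < 4)
    stop("fit_wave_speed: need at least 4 front points", call. = FALSE)
  if (is.null(keep))
    keep <- if (trim) trim_linear_portion(front$x, front$t, trim_tol) else
      seq_along(front$x)
  fit <- stats::lm(front$t[keep] ~ front$x[keep])
  sm <- suppressWarnings(summary(fit))
  slope <- stats::coef(fit)[2]
  slope_sd <- sm$coefficients[2, 2]
  flag <- if (!is.finite(slope) || slope <= 0) "unphysical" else NULL
  v <- if (is.null(flag)) 1 / slope else NA_real_
  sd_v <- if (is.null(flag)) slope_sd / slope^2 else NA_real_
  structure(list(v = unname(v), sd = unname(sd_v), slope = unname(slope),
                 slope_sd = unname(slope_sd), r2 = sm$r.squared,
                 n = length(keep), flag = flag),
            class = "speed_fit")
}

#' Spatial and temporal decay constants along a phase front
#'
#' Log-linear regressions of the front amplitude on time (slope: signed
#' temporal decay constant `Gamma_t`, negative for decaying waves) and on
#' absolute distance (negated slope: spatial decay constant `K`).
#' Amplitudes that are not positive are dropped with a message. The same
#' linear-portion restriction as in [fit_wave_speed()] applies.
#'
#' @param front A `wave_front`.
#' @param x_window Optional distance window `c(lo, hi)` (mm): only front
#'   points with `lo < |x| <= hi` enter the regressions.
#' @param trim Restrict to the linear portion (default TRUE).
#' @param trim_tol Relative slope-change tolerance.
#' @param keep Optional explicit point indices to fit (overrides `trim`;
#'   indices refer to the front after any `x_window` restriction).
#' @return A list of class `decay_fit`: `Gamma_t`, `sd_Gamma` (1/s,
#'   signed), `K`, `sd_K` (1/mm), `r2_t`, `r2_x`, `n`, `flag`.
#' @export
fit_decay <- function(front, x_window = NULL, trim = TRUE, trim_tol = 0.02,
                      keep = NULL) {
  if (!is.null(front$flag))
    return(structure(list(Gamma_t = NA_real_, sd_Gamma = NA_real_, K = NA_real_,
                          sd_K = NA_real_, r2_t = NA_real_, r2_x = NA_real_,
                          n = 0L, flag = front$flag), class = "decay_fit"))
  xs <- front$x; ts <- front$t; as_ <- front$amplitude
  if (!is.null(x_window)) {
    sel <- xs > x_window[1] & xs <= x_window[2]
    xs <- xs[sel]; ts <- ts[sel]; as_ <- as_[sel]
  }
  bad <- !(as_ > 0)
  if (any(bad)) {
    message(sprintf("fit_decay: dropping %d non-positive amplitude point(s)",
                    sum(bad)))
    xs <- xs[!bad]; ts <- ts[!bad]; as_ <- as_[!bad]
  }
  if (length(xs) < 3)
    stop("fit_decay: fewer than 3 usable front points", call. = FALSE)
  la <- log(as_)
  if (is.null(keep))
    keep <- if (trim) trim_linear_portion(xs, la, trim_tol,
                                          nmin = min(4, length(xs)))
            else seq_along(xs)
  keep <- keep[keep <= length(xs)]
  ft <- stats::lm(la[keep] ~ ts[keep])
  fx <- stats::lm(la[keep] ~ xs[keep])
  st <- suppressWarnings(summary(ft)); sx <- suppressWarnings(summary(fx))
  structure(list(Gamma_t = unname(stats::coef(ft)[2]),
                 sd_Gamma = st$coefficients[2, 2],
                 K = -unname(stats::coef(fx)[2]),
                 sd_K = sx$coefficients[2, 2],
                 r2_t = st$r.squared, r2_x = sx$r.squared,
                 n = length(keep), flag = NULL),
            class = "decay_fit")
}

#' Spatial FWHM of the response envelope
#'
#' Full width at half maximum of the spatial profile of the amplitude at
#' the analysis frequency: the per-position Fourier amplitude at the bin
#' nearest `f0`, interpolated linearly around the half-maximum crossings.
#' A multi-peaked profile yields the widest contiguous half-maximum span
#' and a `multipeak` flag.
#'
#' @param avg An `avg_response`, or matrix with `t`, `x` supplied.
#' @param t,x Time/position vectors for bare matrices.
#' @param f0 Analysis frequency (Hz); `NULL` uses the peak bin.
#' @return A list of class `fwhm_estimate`: `fwhm` (mm), `profile`, `x`,
#'   `f0`, `flag`.
#' @export
estimate_fwhm <- function(avg, t = NULL, x = NULL, f0 = NULL) {
  if (inherits(avg, "avg_response")) { y <- avg$y; t <- avg$t; x <- avg$x }
  else y <- avg
  dt <- t[2] - t[1]
  nt <- ncol(y)
  ok <- apply(is.finite(y), 1, all)
  amp <- rep(NA_real_, nrow(y))
  sp <- Mod(t(stats::mvfft(t(y[ok, , drop = FALSE] -
                               rowMeans(y[ok, , drop = FALSE])))))
  pos <- 2:(nt %/% 2 + 1)
  freqs <- (pos - 1) / (nt * dt)
  sel <- pick_bin(freqs, f0, colMeans(sp[, pos, drop = FALSE]^2))
  amp[ok] <- sp[, pos[sel$bin]]
  prof <- amp
  ipk <- which.max(prof)
  half <- prof[ipk] / 2
  above <- prof >= half & is.finite(prof)
  runs <- rle(above)
  nruns <- sum(runs$values, na.rm = TRUE)
  flag <- if (nruns > 1) "multipeak" else NULL
  # widest contiguous above-half run, with sub-bin interpolation at its ends
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  wi <- which(runs$values)
  wi <- wi[which.max(runs$lengths[wi])]
  i1 <- starts[wi]; i2 <- ends[wi]
  xl <- if (i1 > 1 && is.finite(prof[i1 - 1]))
    x[i1 - 1] + (x[i1] - x[i1 - 1]) * (half - prof[i1 - 1]) / (prof[i1] - prof[i1 - 1])
  else x[i1]
  xr <- if (i2 < length(x) && is.finite(prof[i2 + 1]))
    x[i2] + (x[i2 + 1] - x[i2]) * (half - prof[i2]) / (prof[i2 + 1] - prof[i2])
  else x[i2]
  structure(list(fwhm = xr - xl, profile = prof, x = x, f0 = sel$f0,
                 flag = flag),
            class = "fwhm_estimate")
}
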
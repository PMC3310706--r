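#' Zero-phase low-pass filter
#'
#' Third-order Butterworth low-pass applied forward and backward
#' (zero-phase), matching the preprocessing applied to the empirical voxel
#' time series. Zero phase matters here because phase-front timing is the
#' measurement: a one-pass filter would add a frequency-dependent delay.
#' Two passes square the magnitude response, so the attenuation at
#' frequency `f` is `1 / (1 + (f / cutoff)^(2 * order))`.
#'
#' @param ts Numeric vector, or matrix with one time series per row.
#' @param dt Sampling interval (s).
#' @param cutoff Cutoff frequency (Hz), default 0.1.
#' @param order Filter order, default 3.
#' @return Filtered series, same shape as `ts`.
#' @export
lowpass_filter <- function(ts, dt, cutoff = 0.1, order = 3) {
  ny <- 1 / (2 * dt)
  if (cutoff >= ny)
    stop(sprintf("lowpass_filter: cutoff (%g Hz) must be below Nyquist (%g Hz)",
                 cutoff, ny), call. = FALSE)
  bf <- signal::butter(order, cutoff / ny, type = "low")
  # reflect-pad both ends so the forward-backward pass has settled initial
  # conditions; the mean is removed first so padding joins smoothly
  ff <- function(v) {
    n <- length(v)
    np <- min(n - 1, ceiling(3 / (cutoff * dt)))
    mu <- mean(v)
    v <- v - mu
    ext <- c(2 * v[1] - v[(np + 1):2], v, 2 * v[n] - v[(n - 1):(n - np)])
    out <- signal::filtfilt(bf, ext)
    out[(np + 1):(np + n)] + mu
  }
  if (is.matrix(ts)) t(apply(ts, 1, ff)) else ff(ts)
}

#' Analytic signal via the temporal Hilbert transform
#'
#' Returns the complex analytic signal `x + i * H(x)` where `H` is the
#' Hilbert transform, computed by one-sided spectral weighting (zeroing
#' negative frequencies and doubling positive ones). The argument of the
#' analytic signal is the instantaneous phase; its modulus, the envelope.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Unwrap a phase series
#'
#' Removes jumps greater than pi by adding multiples of 2 pi, yielding a
#' continuous phase trajectory.
#'
#' @param p Phase values (radians).
#' @return Unwrapped phase.
#' @export
unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1], dp))
}

# stimulus-locked epoch average: one column per time point within the
# repetition period, averaged over blocks
fold_epochs <- function(mat, tvec, onsets, period, dt) {
  ne <- floor(period / dt)
  acc <- matrix(0, nrow(mat), ne)
  nused <- 0
  for (on in onsets) {
    i0 <- round((on - tvec[1]) / dt) + 1L
    if (i0 < 1 || i0 + ne - 1 > ncol(mat)) next
    acc <- acc + mat[, i0:(i0 + ne - 1)]
    nused <- nused + 1
  }
  if (nused == 0) stop("fold_epochs: no complete epochs in the record", call. = FALSE)
  list(epoch = acc / nused, t = (seq_len(ne) - 1) * dt, n_epochs = nused)
}
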
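#' Normalized Fourier power map and response mask
#'
#' Per-voxel normalized temporal Fourier power: the power in the analysis
#' frequency bin divided by the total power over all positive-frequency
#' bins (DC excluded). Voxels responding at the stimulus frequency approach
#' 1; white noise averages `1 / n_bins`. The response mask thresholds the
#' map at `threshold` (default 0.40).
#'
#' If `f0` does not fall exactly on the frequency grid the nearest bin is
#' used and the offset recorded in the result (`bin_offset_hz`). With
#' `f0 = NULL` the peak bin of the voxel-mean spectrum is used (the
#' empirical peak response frequency).
#'
#' @param ds A [make_flatmap_dataset()] object (or compatible list with
#'   `y`, `t`).
#' @param f0 Analysis frequency (Hz) or `NULL` to detect the peak bin.
#' @param threshold Mask threshold, default 0.40.
#' @return A list of class `response_map`: `map` (nx x ny), `mask`
#'   (logical), `f0` (frequency used), `bin_offset_hz`, `freqs`.
#' @export
response_power_map <- function(ds, f0 = NULL, threshold = 0.40) {
  d <- dim(ds$y)
  mat <- matrix(ds$y, d[1] * d[2], d[3])
  mat <- mat - rowMeans(mat)
  sp <- Mod(t(stats::mvfft(t(mat))))^2
  nt <- d[3]
  dt <- ds$t[2] - ds$t[1]
  pos <- 2:(nt %/% 2 + 1)          # positive-frequency bins, DC excluded
  freqs <- (pos - 1) / (nt * dt)
  pw <- sp[, pos, drop = FALSE]
  sel <- pick_bin(freqs, f0, colMeans(pw))
  map <- pw[, sel$bin] / rowSums(pw)
  map[!is.finite(map)] <- 0
  structure(list(map = matrix(map, d[1], d[2]),
                 mask = matrix(map > threshold, d[1], d[2]),
                 f0 = sel$f0, bin_offset_hz = sel$offset, freqs = freqs,
                 threshold = threshold),
            class = "response_map")
}

pick_bin <- function(freqs, f0, mean_power) {
  if (is.null(f0)) {
    bin <- which.max(mean_power)
    list(bin = bin, f0 = freqs[bin], offset = 0)
  } else {
    bin <- which.min(abs(freqs - f0))
    off <- freqs[bin] - f0
    if (abs(off) > 1e-9)
      message(sprintf("response frequency %.4g Hz not on the grid; using nearest bin %.4g Hz",
                      f0, freqs[bin]))
    list(bin = bin, f0 = freqs[bin], offset = off)
  }
}

#' Stimulus coherence map
#'
#' Magnitude coherence at the analysis frequency between each voxel time
#' series and a reference time course (by default the stimulus envelope
#' convolved with a canonical temporal HRF). The record is split into
#' segments (default three per stimulus block) and the coherence is the
#' modulus of the segment-averaged cross-spectrum normalized by the
#' segment-averaged auto-spectra, so independent noise decorrelates toward
#' zero while stimulus-locked voxels stay near 1. Degenerate
#' (zero-variance) voxels get coherence 0.
#'
#' @param ds Dataset as in [response_power_map()].
#' @param reference Optional reference time course (length `nt`).
#' @param f0 Analysis frequency (Hz); `NULL` uses the nominal stimulus
#'   frequency from the dataset.
#' @param threshold Mask threshold, default 0.4.
#' @param n_segments Number of segments; default three per block.
#' @return A list of class `coherence_map`: `map`, `mask`, `f0`.
#' @export
coherence_map <- function(ds, reference = NULL, f0 = NULL, threshold = 0.4,
                          n_segments = NULL) {
  d <- dim(ds$y)
  dt <- ds$t[2] - ds$t[1]
  if (is.null(f0)) f0 <- ds$f0_nominal
  if (is.null(reference)) {
    env <- stimulus_envelope(ds$stimulus, ds$t)
    hrf <- canonical_hrf(seq(0, 30, by = dt))
    reference <- stats::convolve(env, rev(hrf), type = "open")[seq_along(env)]
  }
  if (is.null(n_segments))
    n_segments <- if (!is.null(ds$stimulus)) 3L * ds$stimulus$n_blocks else 24L
  L <- floor(d[3] / n_segments)
  if (L < 4) stop("coherence_map: record too short for segmentation", call. = FALSE)
  ph <- exp(-2i * pi * f0 * (0:(L - 1)) * dt)
  segs <- lapply(seq_len(n_segments), function(s) ((s - 1) * L + 1):(s * L))
  mat <- matrix(ds$y, d[1] * d[2], d[3])
  Xr <- vapply(segs, function(ix) sum((reference[ix] - mean(reference[ix])) * ph),
               complex(1))
  cross <- complex(length.out = nrow(mat))
  pxx <- numeric(nrow(mat))
  for (s in seq_len(n_segments)) {
    seg <- mat[, segs[[s]], drop = FALSE]
    seg <- seg - rowMeans(seg)
    Xv <- as.vector(seg %*% ph)
    cross <- cross + Xv * Conj(Xr[s])
    pxx <- pxx + Mod(Xv)^2
  }
  pyy <- sum(Mod(Xr)^2)
  coh <- Mod(cross) / sqrt(pxx * pyy)
  coh[!is.finite(coh) | pxx == 0] <- 0
  structure(list(map = matrix(coh, d[1], d[2]),
                 mask = matrix(coh > threshold, d[1], d[2]),
                 f0 = f0, threshold = threshold, n_segments = n_segments),
            class = "coherence_map")
}

#' Canonical temporal hemodynamic response function
#'
#' Standard double-gamma HRF (peak near 5 s, undershoot near 15 s),
#' normalized to unit peak. Used only to build the coherence reference
#' time course.
#'
#' @param t Time (s), non-negative.
#' @return HRF values.
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}
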
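#' Run the full wave-analysis pipeline on a flat-map dataset
#'
#' Composes the empirical pipeline: zero-phase low-pass filtering of every
#' voxel time series, response-power and stimulus-coherence masking,
#' AIC-selected polynomial centerline fit, isoeccentric averaging,
#' stimulus-locked epoch averaging, Hilbert-transform instantaneous phase,
#' phase-front extraction through the central peak, and straight-line
#' regressions for speed and spatial/temporal decay on each side (foveal
#' `F`, positive x; peripheral `P`, negative x), plus the spatial FWHM of
#' the response envelope.
#'
#' When the dataset carries ground truth, estimate-vs-truth deltas are
#' included. Stage flags (degenerate masks, undetectable propagation,
#' unphysical slopes) propagate into the report.
#'
#' @param ds A [make_flatmap_dataset()] object (or one read back with
#'   [read_flatmap()]).
#' @param cutoff Low-pass cutoff (Hz).
#' @param x_min,x_max Exclusion radius and averaging extent (mm).
#' @param floor_frac Amplitude floor (fraction of central peak).
#' @param max_order Maximum centerline polynomial order.
#' @param trim Restrict regressions to the linear portion of the front.
#' @return An object of class `wave_estimates`; see Details.
#' @details The returned object contains per-side lists `F` and `P` with
#'   fields `v`, `v_sd`, `Gamma_t`, `Gamma_sd`, `K`, `K_sd`, `consistency`
#'   (`|Gamma_t| / (K v)`), `n`, `flag`; the FWHM estimate; the fitted
#'   centerline; the analysis frequency; and (if available) `truth` and
#'   `deltas`. `fronts`, `phase` and `avg` are attached for inspection.
#' @export
recover_parameters <- function(ds, cutoff = 0.1, x_min = 1, x_max = 10,
                               floor_frac = 0.1, max_order = 5, trim = TRUE) {
  d <- dim(ds$y)
  flags <- character(0)

  fds <- ds
  mat <- matrix(ds$y, d[1] * d[2], d[3])
  mat <- lowpass_filter(mat, dt = ds$t_pitch, cutoff = cutoff)
  fds$y <- array(mat, d)

  pm <- response_power_map(ds)
  cm <- coherence_map(ds)
  mask <- cm$mask
  if (sum(mask) < max_order + 2) {
    mask <- pm$mask
    flags <- c(flags, "coherence mask degenerate; power mask used")
  }
  if (sum(mask) < 3)
    stop("recover_parameters: no stimulus-responsive voxels found", call. = FALSE)
  # anchor the centerline to the primary band: among coherent voxels keep
  # those whose filtered response amplitude reaches half the map peak
  centered <- fds$y - array(rowMeans(fds$y, dims = 2), dim(fds$y))
  amp <- apply(abs(centered), c(1, 2), max)
  strong <- mask & amp >= 0.5 * max(amp[mask])
  if (sum(strong) >= max_order + 2) mask <- strong
  pts <- cbind(x = ds$x[row(mask)[mask]], y = ds$yrow[col(mask)[mask]])
  cl <- fit_centerline(pts, max_order = max_order, weights = amp[mask])

  avg <- isoeccentric_average(fds, cl, x_max = x_max)
  fold <- fold_epochs(avg$y, avg$t, stimulus_onsets(ds$stimulus),
                      stimulus_period(ds$stimulus), ds$t_pitch)
  pf <- analytic_phase(fold$epoch, t = fold$t, x = avg$x, f0 = pm$f0,
                       floor_frac = floor_frac)
  fronts <- extract_phase_front(pf, x_min = x_min, x_max = x_max,
                                floor_frac = floor_frac)

  side_est <- function(front) {
    if (!is.null(front$flag))
      return(list(v = NA, v_sd = NA, Gamma_t = NA, Gamma_sd = NA,
                  K = NA, K_sd = NA, consistency = NA, n = length(front$x),
                  flag = front$flag))
    # one common linear portion for the speed and both decay regressions,
    # trimming the innermost points that curve either the timing or the
    # log-amplitude profile
    keep <- if (trim) {
      k1 <- trim_linear_portion(front$x, front$t)
      k2 <- trim_linear_portion(front$x, log(pmax(front$amplitude, 1e-12)))
      seq(max(min(k1), min(k2)), length(front$x))
    } else seq_along(front$x)
    sp <- fit_wave_speed(front, keep = keep)
    if (!is.null(sp$flag) && sp$flag == "no detectable propagation")
      return(list(v = NA, v_sd = NA, Gamma_t = NA, Gamma_sd = NA,
                  K = NA, K_sd = NA, consistency = NA, n = sp$n,
                  flag = sp$flag))
    dc <- fit_decay(front, keep = keep)
    cons <- if (is.finite(sp$v) && is.finite(dc$K) && dc$K > 0)
      abs(dc$Gamma_t) / (dc$K * sp$v) else NA_real_
    cons_flag <- NULL
    if (is.finite(cons)) {
      rel_sd <- sqrt((dc$sd_Gamma / max(abs(dc$Gamma_t), 1e-12))^2 +
                       (dc$sd_K / max(dc$K, 1e-12))^2 +
                       (sp$sd / max(sp$v, 1e-12))^2)
      if (abs(cons - 1) > 3 * max(rel_sd, 1e-3))
        cons_flag <- "decay-speed consistency violated"
    }
    list(v = sp$v, v_sd = sp$sd, Gamma_t = dc$Gamma_t, Gamma_sd = dc$sd_Gamma,
         K = dc$K, K_sd = dc$sd_K, consistency = cons,
         n = sp$n, flag = c(sp$flag, dc$flag, cons_flag))
  }
  estF <- side_est(fronts$F)
  estP <- side_est(fronts$P)
  fw <- estimate_fwhm(avg, f0 = pm$f0)

  out <- list(F = estF, P = estP, fwhm = fw$fwhm, fwhm_flag = fw$flag,
              centerline = cl, f0 = pm$f0, n_epochs = fold$n_epochs,
              flags = flags)
  if (length(ds$ground_truth) && !is.null(ds$ground_truth$v_beta)) {
    gt <- ds$ground_truth
    delta_of <- function(e) c(
      v = if (is.finite(e$v)) (e$v - gt$v_beta) / gt$v_beta else NA,
      Gamma = if (is.finite(e$Gamma_t)) (abs(e$Gamma_t) - gt$Gamma) / gt$Gamma else NA,
      K = if (is.finite(e$K)) (e$K - gt$K) / gt$K else NA)
    out$truth <- gt
    out$deltas <- list(F = delta_of(estF), P = delta_of(estP))
  }
  structure(out, fronts = fronts, phase = pf, avg = avg,
            class = "wave_estimates")
}

#' @export
print.wave_estimates <- function(x, ...) {
  cat("<wave_estimates> analysis frequency", signif(x$f0, 3), "Hz\n")
  show <- function(e, side) {
    if (!is.null(e$flag) && length(e$flag))
      cat(sprintf("  %s: %s\n", side, paste(e$flag, collapse = "; ")))
    if (is.finite(e$v))
      cat(sprintf("  %s: v = %.2f +/- %.2f mm/s, Gamma_t = %.3f +/- %.3f 1/s, K = %.3f +/- %.3f 1/mm (n = %d)\n",
                  side, e$v, e$v_sd, e$Gamma_t, e$Gamma_sd, e$K, e$K_sd, e$n))
  }
  show(x$F, "F"); show(x$P, "P")
  cat(sprintf("  FWHM = %.2f mm%s\n", x$fwhm,
              if (!is.null(x$fwhm_flag)) paste0(" [", x$fwhm_flag, "]") else ""))
  if (!is.null(x$deltas)) {
    cat(sprintf("  truth: v = %.2f, Gamma = %.2f; rel. deltas F: %s | P: %s\n",
                x$truth$v_beta, x$truth$Gamma,
                paste(sprintf("%s %+.1f%%", names(x$deltas$F), 100 * x$deltas$F),
                      collapse = ", "),
                paste(sprintf("%s %+.1f%%", names(x$deltas$P), 100 * x$deltas$P),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
as.data.frame.wave_estimates <- function(x, ...) {
  row <- function(e, side) data.frame(
    side = side, v = e$v, v_sd = e$v_sd, Gamma_t = e$Gamma_t,
    Gamma_sd = e$Gamma_sd, K = e$K, K_sd = e$K_sd,
    consistency = e$consistency, n = e$n,
    flag = if (is.null(e$flag) || !length(e$flag)) "" else
      paste(e$flag, collapse = "; "))
  df <- rbind(row(x$F, "F"), row(x$P, "P"))
  df$fwhm <- x$fwhm
  df$f0 <- x$f0
  df
}
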
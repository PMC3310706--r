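#' Noise specification for synthetic datasets
#'
#' Additive voxelwise noise: white Gaussian innovations of standard
#' deviation `white_sd` (percent signal) passed through an AR(1) recursion
#' with coefficient `ar1` (stationary standard deviation
#' `white_sd / sqrt(1 - ar1^2)`), plus a slow sinusoidal scanner drift of
#' amplitude `drift` with random frequency (0.003--0.008 Hz) and phase per
#' voxel. `seed` makes the dataset bit-reproducible and is recorded in the
#' output metadata.
#'
#' @param white_sd Innovation standard deviation (percent signal change).
#' @param ar1 AR(1) coefficient in `[0, 1)`.
#' @param drift Drift amplitude (percent signal change).
#' @param seed Integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(white_sd = 0.1 * sqrt(1 - 0.3^2), ar1 = 0.3,
                       drift = 0.05, seed = 1L) {
  stopifnot(white_sd >= 0, ar1 >= 0, ar1 < 1, drift >= 0)
  structure(list(white_sd = white_sd, ar1 = ar1, drift = drift,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Zero-noise specification
#' @export
#' @rdname noise_spec
no_noise <- function() noise_spec(white_sd = 0, ar1 = 0, drift = 0)

#' Generate a synthetic flat-map BOLD dataset
#'
#' Simulates the BOLD response to the Gaussian line stimulus with the
#' linearized model, resamples it to the flat-map acquisition pitch
#' (default 0.75 mm, 0.25 s), adds noise, and packages the result with its
#' ground truth. For a straight centerline the 2-D field is obtained
#' exactly from the 1-D simulation by translational symmetry; a curved
#' (polynomial) centerline triggers a full 2-D spectral simulation.
#'
#' @param pars A [wave_params()] or [hemo_params()] object (the ground
#'   truth). `a_F = NA` is calibrated automatically.
#' @param spec A [stimulus_spec()].
#' @param centerline Polynomial coefficients of the centerline `x = f(y)`
#'   (a single number gives a straight line).
#' @param noise A [noise_spec()]; use [no_noise()] for a noiseless dataset.
#' @param pitch Voxel pitch of the output (mm).
#' @param t_pitch Temporal sampling of the output (s).
#' @param x_halfwidth Half-extent of the output map perpendicular to the
#'   line (mm).
#' @param y_extent Extent along the line (mm).
#' @param tail Post-paradigm rest retained (s).
#' @param sim_dx Simulation spatial step (mm); must divide `pitch`.
#' @return An object of class `flatmap_dataset`: the data array `y`
#'   (`nx * ny * nt`, percent signal change), coordinates `x`, `yrow`, `t`,
#'   the true `centerline`, `ground_truth` (parameters, stimulus, noise),
#'   and acquisition metadata.
#' @export
make_flatmap_dataset <- function(pars, spec = stimulus_spec(),
                                 centerline = 0, noise = noise_spec(),
                                 pitch = 0.75, t_pitch = 0.25,
                                 x_halfwidth = 24, y_extent = 18,
                                 tail = 6, sim_dx = pitch / 2) {
  pars <- ensure_gain(pars)
  cc <- chain_constants(pars)
  straight <- length(centerline) == 1 ||
    all(abs(centerline[-1]) < 1e-12)
  x0 <- centerline[1]
  duration <- spec$lead_in + spec$n_blocks * stimulus_period(spec) + tail
  nt_out <- floor(duration / t_pitch)
  nxo <- 2L * floor(x_halfwidth / pitch) + 1L
  nyo <- 2L * floor(y_extent / 2 / pitch) + 1L
  xout <- (seq_len(nxo) - 1 - nxo %/% 2) * pitch
  yout <- (seq_len(nyo) - 1 - nyo %/% 2) * pitch

  rx <- round(pitch / sim_dx)
  if (abs(rx * sim_dx - pitch) > 1e-9)
    stop("make_flatmap_dataset: sim_dx must divide pitch", call. = FALSE)
  rt <- max(1L, round(t_pitch / 0.25))

  if (straight) {
    Lh <- pad_halfwidth(cc$v, cc$Gamma, x_halfwidth + abs(x0))
    nx <- 2^ceiling(log2(2 * Lh / sim_dx))
    nt <- 2^ceiling(log2(duration / 0.25))
    g <- st_grid(dx = sim_dx, dt = 0.25, nx = nx, nt = nt)
    z <- line_stimulus(spec, centerline = x0, grid = g)
    y1 <- simulate_response(z, pars, g)$values
    ix <- vapply(xout, function(xx) which.min(abs(g$x - xx)), 1L)
    it <- seq(1L, by = rt, length.out = nt_out)
    ysig <- y1[ix, it]
    ydat <- array(ysig, c(nxo, nt_out, nyo))
    ydat <- aperm(ydat, c(1, 3, 2))
    tvec <- g$t[it]
  } else {
    sdx <- pitch  # full 2-D run at voxel pitch
    Lh <- pad_halfwidth(cc$v, cc$Gamma, x_halfwidth + max(abs(centerline[1]), 1))
    nx <- 2^ceiling(log2(2 * Lh / sdx))
    ny <- 2^ceiling(log2((y_extent + 24) / sdx))
    nt <- 2^ceiling(log2(duration / 0.25))
    g <- st_grid(dx = sdx, dt = 0.25, nx = nx, nt = nt, ny = ny)
    z <- line_stimulus(spec, centerline = centerline, grid = g)
    yf <- simulate_response(z, pars, g)$values
    ix <- vapply(xout, function(xx) which.min(abs(g$x - xx)), 1L)
    iy <- vapply(yout, function(yy) which.min(abs(g$y - yy)), 1L)
    it <- seq(1L, by = rt, length.out = nt_out)
    ydat <- yf[ix, iy, it]
    tvec <- g$t[it]
  }

  if (noise$white_sd > 0 || noise$drift > 0) {
    ydat <- ydat + withr::with_seed(noise$seed,
                                    make_noise(noise, nxo, nyo, nt_out, tvec))
  }

  gt_pars <- if (inherits(pars, "wave_params")) pars else derive_reduced_params(pars)
  structure(list(
    y = ydat, x = xout, yrow = yout, t = tvec,
    pitch = pitch, t_pitch = t_pitch,
    centerline = as.numeric(centerline),
    stimulus = spec, noise = noise,
    ground_truth = list(v_beta = gt_pars$v_beta, Gamma = gt_pars$Gamma,
                        omega_D = gt_pars$omega_D,
                        a_F = if (inherits(pars, "wave_params")) pars$a_F else NA,
                        K = gt_pars$Gamma / gt_pars$v_beta),
    f0_nominal = 1 / stimulus_period(spec),
    seed = noise$seed),
    class = "flatmap_dataset")
}

make_noise <- function(noise, nx, ny, nt, tvec) {
  nvox <- nx * ny
  e <- matrix(stats::rnorm(nvox * nt, sd = noise$white_sd), nvox, nt)
  if (noise$ar1 > 0)
    e <- t(apply(e, 1, function(r) stats::filter(r, noise$ar1,
                                                 method = "recursive")))
  if (noise$drift > 0) {
    fr <- stats::runif(nvox, 0.003, 0.008)
    ph <- stats::runif(nvox, 0, 2 * pi)
    e <- e + noise$drift * sin(outer(2 * pi * fr, tvec) + ph)
  }
  array(e, c(nx, ny, nt))
}

#' @export
print.flatmap_dataset <- function(x, ...) {
  cat(sprintf("<flatmap_dataset> %d x %d voxels (%g mm) x %d volumes (%g s)\n",
              length(x$x), length(x$yrow), x$pitch, length(x$t), x$t_pitch))
  if (!is.null(x$ground_truth))
    cat(sprintf("  ground truth: v_beta = %.3g mm/s, Gamma = %.3g 1/s; noise seed %d\n",
                x$ground_truth$v_beta, x$ground_truth$Gamma, x$seed))
  invisible(x)
}

#' Write / read a flat-map dataset (NIfTI + JSON sidecar)
#'
#' The data array is written as a NIfTI volume (`<prefix>.nii`, dimensions
#' x, y, 1, t with pixel dimensions `pitch, pitch, 1, t_pitch`) and all
#' remaining fields -- ground truth, stimulus, noise, coordinates, seed --
#' as a JSON sidecar (`<prefix>.json`). `read_flatmap()` reconstructs the
#' dataset object; ground truth round-trips exactly to JSON precision.
#'
#' @param ds A [make_flatmap_dataset()] object.
#' @param prefix Output path prefix.
#' @return `write_flatmap()`: the prefix, invisibly. `read_flatmap()`: the
#'   dataset.
#' @export
write_flatmap <- function(ds, prefix) {
  arr <- array(ds$y, c(dim(ds$y)[1], dim(ds$y)[2], 1, dim(ds$y)[3]))
  img <- RNifti::asNifti(arr, pixdim = c(ds$pitch, ds$pitch, 1, ds$t_pitch))
  RNifti::writeNifti(img, paste0(prefix, ".nii"))
  side <- list(x = ds$x, yrow = ds$yrow, t = ds$t, pitch = ds$pitch,
               t_pitch = ds$t_pitch, centerline = ds$centerline,
               stimulus = unclass(ds$stimulus), noise = unclass(ds$noise),
               ground_truth = ds$ground_truth, f0_nominal = ds$f0_nominal,
               seed = ds$seed)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_flatmap
#' @export
read_flatmap <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  arr <- array(as.numeric(img), dim(img))
  structure(list(
    y = array(arr, dim(arr)[c(1, 2, 4)]),
    x = side$x, yrow = side$yrow, t = side$t,
    pitch = side$pitch, t_pitch = side$t_pitch,
    centerline = side$centerline,
    stimulus = do.call(stimulus_spec, side$stimulus[c("sigma_x", "on_duration",
                                                      "off_duration", "n_blocks",
                                                      "dephase_step", "lead_in")]),
    noise = do.call(noise_spec, side$noise[c("white_sd", "ar1", "drift", "seed")]),
    ground_truth = side$ground_truth,
    f0_nominal = side$f0_nominal, seed = side$seed),
    class = "flatmap_dataset")
}
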
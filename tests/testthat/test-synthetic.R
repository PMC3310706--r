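test_that("the line stimulus has the configured Gaussian cross-section and timing", {
  spec <- stimulus_spec()
  g <- st_grid(dx = 0.25, dt = 0.25, nx = 128, nt = 800)
  z <- line_stimulus(spec, centerline = 0, grid = g)
  on1 <- which(z$values[grid_origin(g)["ix"], ] > 0)[1]
  expect_equal(z$values[, on1], exp(-g$x^2 / (2 * spec$sigma_x^2)))

  # block b onset shifted by b * 0.25 s beyond the nominal cadence
  ons <- stimulus_onsets(spec)
  nominal <- spec$lead_in + (0:7) * (spec$on_duration + spec$off_duration)
  expect_equal(ons - nominal, (0:7) * 0.25)

  # duty cycle of the on/off cycle
  expect_equal(spec$on_duration / (spec$on_duration + spec$off_duration),
               8 / 20.25)
  env <- hemowave:::stimulus_envelope(spec, g$t)
  expect_equal(sum(env) * g$dt, spec$n_blocks * spec$on_duration)

  expect_error(line_stimulus(spec, centerline = 100, grid = g), "outside")
})

test_that("2-D stimulus cross-sections are Gaussian perpendicular to the line", {
  spec <- stimulus_spec(n_blocks = 1, lead_in = 2)
  g <- st_grid(dx = 0.5, dt = 0.5, nx = 64, nt = 16, ny = 32)
  z <- line_stimulus(spec, centerline = c(2), grid = g)
  it <- which(hemowave:::stimulus_envelope(spec, g$t) > 0)[1]
  for (iy in c(1, 16, 32))
    expect_equal(z$values[, iy, it], exp(-(g$x - 2)^2 / 2), tolerance = 1e-12)
  expect_error(line_stimulus(spec, centerline = c(0, 0, 0.5), grid = g),
               "exits")
})

test_that("datasets regenerate bit-identically from their seed", {
  d1 <- quick_dataset(3, 0.8, noise = noise_spec(seed = 11))
  d2 <- quick_dataset(3, 0.8, noise = noise_spec(seed = 11))
  expect_identical(d1$y, d2$y)
  d3 <- quick_dataset(3, 0.8, noise = noise_spec(seed = 12))
  expect_false(identical(d3$y, d1$y))
})

test_that("straight-centerline datasets are translation invariant", {
  ds <- quick_dataset(3, 0.8)
  for (iy in seq_along(ds$yrow)[-1])
    expect_identical(ds$y[, iy, ], ds$y[, 1, ])
  # and each row is the 1-D spectral solution evaluated at the voxel grid
  tr <- ds$y[which.min(abs(ds$x)), 1, ]
  expect_equal(max(abs(tr)), 0.4, tolerance = 0.02)  # calibrated amplitude
})

test_that("noise in a stimulus-free margin matches the AR(1) prediction", {
  ns <- noise_spec(white_sd = 0.08, ar1 = 0.4, drift = 0, seed = 3)
  ds <- quick_dataset(3, 0.8, noise = ns)
  expect_gte(length(ds$t), 700)
  margin <- abs(ds$x) > 20
  sds <- apply(ds$y[margin, , ], c(1, 2), sd)
  expect_equal(mean(sds), ns$white_sd / sqrt(1 - ns$ar1^2), tolerance = 0.1)
})

test_that("datasets round-trip through NIfTI plus sidecar", {
  ds <- quick_dataset(2.3, 0.86, noise = noise_spec(seed = 2))
  pre <- file.path(tempdir(), "rt")
  write_flatmap(ds, pre)
  back <- read_flatmap(pre)
  expect_equal(back$y, ds$y, tolerance = 1e-6)
  expect_equal(back$ground_truth$v_beta, 2.3)
  expect_equal(back$ground_truth$Gamma, 0.86)
  expect_equal(back$stimulus$off_duration, 12.25)
  expect_equal(back$noise$seed, 2L)
  expect_equal(back$t, ds$t)
})

test_that("a curved centerline is recovered to sub-voxel accuracy", {
  cl <- c(0.5, 0.05, 0.02, 0.002)
  ds <- make_flatmap_dataset(wave_params(3, 0.8, a_F = 1),
                             stimulus_spec(n_blocks = 4), centerline = cl,
                             noise = no_noise(), x_halfwidth = 15,
                             y_extent = 12)
  est <- quiet_recover(ds)
  cf <- est$centerline$coef
  yy <- seq(-6, 6, by = 0.75)
  rms <- sqrt(mean((hemowave:::polyval_asc(cl, yy) -
                      hemowave:::polyval_asc(cf, yy))^2))
  expect_lt(rms / ds$pitch, 0.5)
  # averaged response close to the 1-D (straight-line) truth
  ds1 <- make_flatmap_dataset(wave_params(3, 0.8, a_F = 1),
                              stimulus_spec(n_blocks = 4), centerline = 0,
                              noise = no_noise(), x_halfwidth = 15,
                              y_extent = 12)
  avg <- attr(est, "avg")
  truth <- lowpass_filter(ds1$y[, 1, ], dt = ds1$t_pitch)  # like for like
  ix <- match(round(avg$x / 0.75), round(ds1$x / 0.75))
  ok <- is.finite(avg$y[, 1]) & !is.na(ix)
  err <- max(abs(avg$y[ok, ] - truth[ix[ok], ]))
  expect_lt(err, 0.05 * max(abs(truth)))
})
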
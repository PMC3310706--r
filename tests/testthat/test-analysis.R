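test_that("zero-phase Butterworth filtering matches its closed-form response", {
  dt <- 0.25
  t <- seq(0, 400, by = dt)
  expect_equal(lowpass_filter(rep(2.5, length(t)), dt), rep(2.5, length(t)),
               tolerance = 1e-9)
  # two-pass attenuation at 2 x cutoff: 1 / (1 + 2^6) = 1/65
  s <- sin(2 * pi * 0.2 * t)
  f <- lowpass_filter(s, dt)
  mid <- t > 100 & t < 300
  att <- max(abs(f[mid])) / 1
  expect_equal(att, 1 / 65, tolerance = 0.1)
  # linearity
  a <- rnorm(length(t)); b <- rnorm(length(t))
  expect_equal(lowpass_filter(a + b, dt),
               lowpass_filter(a, dt) + lowpass_filter(b, dt), tolerance = 1e-9)
  expect_error(lowpass_filter(s, dt, cutoff = 2.5), "Nyquist")
})

test_that("the analytic signal reproduces Hilbert-transform identities", {
  dt <- 0.1
  t <- seq(0, 200 - dt, by = dt)
  f0 <- 0.1
  a <- analytic_signal(cos(2 * pi * f0 * t))
  # quadrature: imaginary part is sin
  mid <- seq(100, length(t) - 100)
  expect_equal(Im(a)[mid], sin(2 * pi * f0 * t)[mid], tolerance = 1e-3)
  # unwrapped phase advances at 2 pi f0 per second
  ph <- unwrap_phase(Arg(a))
  slope <- coef(lm(ph[mid] ~ t[mid]))[2]
  expect_equal(unname(slope), 2 * pi * f0, tolerance = 1e-4)
})

test_that("a traveling sinusoid has phase gradient -2 pi f0 / v", {
  dt <- 0.25; f0 <- 0.05; v <- 2
  t <- seq(0, 160 - dt, by = dt)
  x <- seq(-8, 8, by = 0.75)
  y <- outer(x, t, function(xx, tt) cos(2 * pi * f0 * (tt - xx / v)))
  pf <- analytic_phase(y, t = t, x = x, f0 = f0)
  imid <- length(t) %/% 2
  phx <- unwrap_phase(pf$phi[, imid])
  g <- coef(lm(phx ~ x))[2]
  expect_equal(unname(g), -2 * pi * f0 / v, tolerance = 1e-3)
})

test_that("normalized power concentrates for sinusoids and spreads for noise", {
  dt <- 0.25; nt <- 800
  t <- (0:(nt - 1)) * dt
  f0 <- 10 / (nt * dt)      # exactly on the grid
  mk_ds <- function(mat) list(y = array(mat, c(nrow(mat), 1, nt)), t = t)
  pure <- matrix(sin(2 * pi * f0 * t), 1, byrow = TRUE)
  pm <- response_power_map(mk_ds(pure), f0 = f0)
  expect_gt(pm$map[1, 1], 0.999)
  set.seed(8)
  noise <- matrix(rnorm(200 * nt), 200, nt)
  pmn <- response_power_map(mk_ds(noise), f0 = f0)
  nbins <- length(pmn$freqs)
  expect_equal(mean(pmn$map), 1 / nbins, tolerance = 0.15)
  expect_false(any(pmn$mask))
})

test_that("coherence is 1 for scaled copies and small for independent noise", {
  ds <- quick_dataset(3, 0.8, noise = noise_spec(seed = 4))
  ref <- 3 * sin(2 * pi * ds$f0_nominal * ds$t) + 1
  one <- list(y = array(rep(0.2 * ref - 4, each = 1), c(1, 1, length(ds$t))),
              t = ds$t, f0_nominal = ds$f0_nominal, stimulus = ds$stimulus)
  cm1 <- coherence_map(one, reference = ref)
  expect_equal(cm1$map[1, 1], 1, tolerance = 1e-10)
  # degenerate voxel
  zero <- one; zero$y[] <- 5
  expect_equal(coherence_map(zero, reference = ref)$map[1, 1], 0)
  # independent noise exceeds the 0.4 threshold rarely
  set.seed(9)
  nvox <- 400
  noisy <- list(y = array(rnorm(nvox * length(ds$t)), c(nvox, 1, length(ds$t))),
                t = ds$t, f0_nominal = ds$f0_nominal, stimulus = ds$stimulus)
  cmn <- coherence_map(noisy, reference = ref)
  expect_gt(mean(cmn$map <= 0.4), 0.95)
})

test_that("masks trace the stimulated band on synthetic data", {
  ds <- quick_dataset(2.3, 0.86, noise = noise_spec(seed = 6))
  pm <- response_power_map(ds)
  cm <- coherence_map(ds)
  near <- abs(ds$x) <= 1.5
  far <- abs(ds$x) >= 18
  expect_gt(mean(pm$mask[near, ]), 0.6)   # noise dilutes normalized power
  expect_true(all(cm$mask[near, ]))
  expect_lt(mean(pm$mask[far, ]), 0.25)
  expect_lt(mean(cm$mask[far, ]), 0.25)
})

test_that("AIC polynomial selection finds the generating order", {
  # exact cubic: order 3, essentially zero residual
  yv <- seq(-6, 6, by = 0.4)
  xv <- 0.3 - 0.2 * yv + 0.05 * yv^2 + 0.01 * yv^3
  fit <- fit_centerline(cbind(xv, yv))
  expect_equal(fit$order, 3)
  expect_lt(fit$rss[3], 1e-18)
  expect_equal(fit$coef, c(0.3, -0.2, 0.05, 0.01), tolerance = 1e-8)

  # noisy straight line selects order 1 (tie-break favors the lower order)
  set.seed(21)
  hits <- 0
  for (i in 1:20) {
    x2 <- 0.5 + 0.1 * yv + rnorm(length(yv), sd = 0.4)
    f2 <- fit_centerline(cbind(x2, yv))
    hits <- hits + (f2$order == 1)
  }
  expect_gte(hits, 18)
})

test_that("near-degenerate geometry falls back to swapped axes", {
  xv <- seq(-6, 6, by = 0.5)           # band along x, flat in y
  yv <- 0.2 * xv + rnorm(length(xv), sd = 0.1)
  expect_message(fit <- fit_centerline(cbind(xv, yv)), "swapped")
  expect_true(fit$swapped)
})

test_that("isoeccentric averaging respects symmetry and missing bins", {
  ds <- quick_dataset(3, 0.8)
  avg <- isoeccentric_average(ds, centerline = 0, x_max = 10)
  i0 <- which.min(abs(avg$x))
  row0 <- ds$y[which.min(abs(ds$x)), 1, ]
  expect_equal(avg$y[i0, ], row0)
  expect_false(any(avg$missing))
  # bins beyond the data margin are missing, not zero
  small <- ds
  keep <- abs(ds$x) <= 6
  small$y <- ds$y[keep, , , drop = FALSE]
  small$x <- ds$x[keep]
  avg2 <- isoeccentric_average(small, centerline = 0, x_max = 10)
  expect_true(any(avg2$missing))
  expect_true(all(is.na(avg2$y[avg2$missing, ])))
})
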
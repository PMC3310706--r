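test_that("simulate_response of a unit impulse reproduces the stHRF", {
  wp <- wave_params(3, 0.8, a_F = 1)
  g <- st_grid(dx = 0.5, dt = 0.25, nx = 64, nt = 128)
  z <- array(0, c(g$nx, g$nt))
  z[grid_origin(g)["ix"], 1] <- 1 / (g$dx * g$dt)
  y <- simulate_response(z, wp, g)
  expect_equal(y$values,
               suppressWarnings(compute_sthrf(wp, g, impulse = "delta"))$values)
})

test_that("responses superpose and shift with their sources", {
  wp <- wave_params(3, 0.8, a_F = 1)
  g <- st_grid(dx = 0.5, dt = 0.25, nx = 64, nt = 128)
  o <- grid_origin(g)["ix"]
  mk <- function(ix, it) { z <- array(0, c(g$nx, g$nt)); z[ix, it] <- 1; z }
  y1 <- simulate_response(mk(o - 8, 3), wp, g)$values
  y2 <- simulate_response(mk(o + 4, 9), wp, g)$values
  ys <- simulate_response(mk(o - 8, 3) + mk(o + 4, 9), wp, g)$values
  expect_equal(ys, y1 + y2, tolerance = 1e-12)
  # the shifted response is the circularly shifted base response
  y0 <- simulate_response(mk(o, 3), wp, g)$values
  expect_equal(y1, y0[((seq_len(g$nx) - 1 + 8) %% g$nx) + 1, ],
               tolerance = 1e-10)
})

test_that("responses are causal and decay within a sufficient window", {
  wp <- wave_params(3, 0.8, a_F = 1)
  g <- st_grid(dx = 0.5, dt = 0.125, nx = 64, nt = 512)  # 64 s window
  # causality for a band-limited pulse centred at t = 8 (3 sigma = 1.2 s)
  z <- outer(g$x, g$t, pulse_zfun, t0 = 8)
  y <- simulate_response(z, wp, g)
  peak <- max(abs(y$values))
  pre <- y$values[, g$t < 8 - 4 * 0.4]
  expect_lt(max(abs(pre)), 1e-3 * peak)
  yh <- compute_sthrf(wp, g, t0 = 8)
  expect_false(attr(yh, "window_short"))
  # a clearly short window raises the flag
  g2 <- st_grid(dx = 0.5, dt = 0.25, nx = 64, nt = 24)
  expect_warning(y2 <- compute_sthrf(wp, g2), "decayed")
  expect_true(attr(y2, "window_short"))
})

test_that("far-field peak latency grows affinely with distance", {
  wp <- wave_params(3, 0.8, a_F = 1)
  g <- st_grid(dx = 0.25, dt = 0.125, nx = 512, nt = 256)
  y <- compute_sthrf(wp, g)
  xs <- seq(3, 8, by = 0.5)
  tpk <- vapply(xs, function(xx) {
    i <- which.min(abs(g$x - xx))
    g$t[which.max(y$values[i, ])]
  }, 1)
  fit <- lm(tpk ~ xs)
  expect_gt(coef(fit)[2], 0)
  expect_lt(max(abs(resid(fit))), 2 * g$dt)   # straight to sampling accuracy
})

test_that("spectral and time-domain solutions agree; oracle converges", {
  wp <- subj_foveal(a_F = 1)
  g <- st_grid(dx = 0.5, dt = 0.2, nx = 32, nt = 128)
  z <- outer(g$x, g$t, pulse_zfun)
  ys <- simulate_response(z, wp, g)
  yo <- time_domain_oracle(pars = wp, grid = g, zfun = pulse_zfun)
  gap <- rel_l2(ys$values, yo$values)
  expect_lt(gap, 1e-3)
  # zero drive -> identically zero
  y0 <- time_domain_oracle(z = array(0, c(g$nx, g$nt)), pars = wp, grid = g)
  expect_true(all(y0$values == 0))
  # halving the internal step changes the oracle by less than the gap
  yo2 <- time_domain_oracle(pars = wp, grid = g, zfun = pulse_zfun, cfl = 0.15)
  expect_lt(rel_l2(yo2$values, yo$values), gap)
})

test_that("the oracle refuses an unstable grid with a suggested step", {
  wp <- wave_params(6, 0.8, a_F = 1)
  g <- st_grid(dx = 0.5, dt = 0.25, nx = 32, nt = 32)
  expect_error(time_domain_oracle(pars = wp, grid = g, zfun = pulse_zfun),
               "dt <= dx / v_beta")
})

test_that("a straight-line 2-D simulation reduces to the 1-D solution", {
  wp <- wave_params(3, 0.8, a_F = 1)
  g2 <- st_grid(dx = 0.75, dt = 0.5, nx = 64, nt = 64, ny = 16)
  g1 <- st_grid(dx = 0.75, dt = 0.5, nx = 64, nt = 64)
  spec <- stimulus_spec(n_blocks = 1, lead_in = 4)
  z2 <- line_stimulus(spec, centerline = c(0), grid = g2)
  z1 <- line_stimulus(spec, centerline = 0, grid = g1)
  y2 <- simulate_response(z2, wp, g2)
  y1 <- simulate_response(z1, wp, g1)
  for (iy in c(1, 8, 16))
    expect_equal(y2$values[, iy, ], y1$values, tolerance = 1e-10)
})

test_that("block stimulation produces a post-stimulus undershoot", {
  wp <- subj_foveal(a_F = 1)
  g <- st_grid(dx = 0.5, dt = 0.25, nx = 256, nt = 512)
  spec <- stimulus_spec(n_blocks = 1, lead_in = 10)
  z <- line_stimulus(spec, centerline = 0, grid = g)
  y <- simulate_response(z, wp, g)
  tr <- y$values[grid_origin(g)["ix"], ]
  post <- g$t > 18 & g$t < 40
  expect_gt(max(tr), 0)
  expect_lt(min(tr[post]), -0.02 * max(tr))   # late negative phase
})

test_that("propagation extent is monotone in speed and damping", {
  sw <- parameter_sweep(c(1, 4), c(0.4, 1.6))
  s <- sw$summary
  for (g in unique(s$Gamma)) {
    e <- s$extent_mm[s$Gamma == g][order(s$v_beta[s$Gamma == g])]
    expect_true(all(diff(e) >= 0))
  }
  for (v in unique(s$v_beta)) {
    e <- s$extent_mm[s$v_beta == v][order(s$Gamma[s$v_beta == v])]
    expect_true(all(diff(e) <= 0))
  }
  # weak-damping, high-stiffness responses span the sheet
  swf <- parameter_sweep(12, 0.2, grid = st_grid(0.5, 0.25, 128, 256))
  expect_gte(swf$summary$extent_mm, 0.45 * 128 * 0.5 / 2)
})
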
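test_that("flow stage is a unit-DC second-order low-pass", {
  p <- hemo_params()
  expect_equal(flow_transfer(0, p), 1 + 0i)
  expect_lt(Mod(flow_transfer(1e3, p)), 1e-5)
  # resonance of the damped second-order filter matches the closed form
  g2 <- function(w) Mod(flow_transfer(w, p))^2
  wr <- sqrt(p$gamma_f - p$kappa^2 / 2)
  opt <- optimize(g2, c(0, 2), maximum = TRUE)
  expect_equal(opt$maximum, wr, tolerance = 1e-4)
  peak <- p$gamma_f^2 / (p$kappa^2 * (p$gamma_f - p$kappa^2 / 4))
  expect_equal(g2(wr), peak, tolerance = 1e-10)
})

test_that("dispersion roots match the damped-wave closed form", {
  r <- wave_params(3, 0.8)
  d0 <- dispersion(0, r)
  expect_equal(sort(Mod(d0)), c(0, 2 * r$Gamma))
  expect_equal(unname(d0[1, "minus"]), -2i * r$Gamma)

  # critically damped mode: double root at -i * Gamma
  kc <- r$Gamma / r$v_beta
  dc <- dispersion(kc, r)
  expect_equal(unname(dc[1, "plus"]), unname(dc[1, "minus"]),
               tolerance = 1e-6)
  expect_equal(unname(dc[1, "plus"]), -1i * r$Gamma, tolerance = 1e-6)

  # far-field phase speed approaches v_beta
  kf <- 10 * r$Gamma / r$v_beta
  df <- dispersion(kf, r)
  ratio <- abs(Re(df[1, "plus"])) / (r$v_beta * kf)
  expect_gte(ratio, 0.99); expect_lte(ratio, 1)

  # stability and monotone phase speed
  ks <- seq(0.05, 5, by = 0.05)
  dd <- dispersion(ks, r)
  expect_true(all(Im(dd) <= 1e-12))
  vph <- abs(Re(dd[, "plus"])) / ks
  run <- vph[vph > 0]
  expect_true(all(diff(run) >= -1e-9))
  expect_lt(max(vph), r$v_beta + 1e-9)
})

test_that("transfer sets are Hermitian-symmetric and finite", {
  g <- st_grid(dx = 0.5, dt = 0.25, nx = 32, nt = 64)
  for (pars in list(wave_params(2.3, 0.86, a_F = 1), hemo_params(),
                    wave_params(3, 0.8, a_F = 1, omega_D = 0))) {
    tf <- assemble_transfer_functions(pars, g)
    for (nm in c("T_Fz", "T_xiz", "T_Qz", "T_yz")) {
      Tz <- tf[[nm]]
      expect_true(all(is.finite(Re(Tz))), info = nm)
      flip <- Tz[c(1, 32:2), c(1, 64:2)]
      expect_equal(max(abs(flip - Conj(Tz))), 0, info = nm)
    }
  }
  # odd-length grids have no shared Nyquist bin
  g2 <- st_grid(dx = 0.5, dt = 0.25, nx = 31, nt = 63)
  tf <- assemble_transfer_functions(wave_params(3, 0.8, a_F = 1), g2)
  flip <- tf$T_yz[c(1, 31:2), c(1, 63:2)]
  expect_lt(max(abs(flip - Conj(tf$T_yz))), 1e-14)
})

test_that("undamped parameter sets are rejected", {
  expect_error(wave_params(3, -0.5), "Gamma")
})

test_that("dHb stage has a single pole at eta + 1/tau", {
  p <- hemo_params()
  # g(omega) * (i*omega + eta + 1/tau) must be affine in omega: the stage
  # is first-order.  With outflow disabled (tau = Inf) the pole is at eta.
  check_pole <- function(tau_override, rate) {
    w <- c(0.1, 0.2, 0.3)
    g <- dhb_transfer(0, w, p, input = "xi", tau_override = tau_override)
    num <- g * (1i * w + rate)
    expect_lt(Mod(num[1] - 2 * num[2] + num[3]), 1e-12)
  }
  check_pole(NULL, p$eta + 1 / p$tau)
  check_pole(Inf, p$eta)
})

test_that("dHb at the source dips before its delayed rise under a step drive", {
  wp <- wave_params(2.3, 0.86, a_F = 1)
  g <- st_grid(dx = 0.5, dt = 0.25, nx = 128, nt = 256)
  z <- outer(exp(-g$x^2 / 2), as.numeric(g$t >= 4 & g$t < 12))
  q <- simulate_response(z, wp, g, quantity = "Q")
  qc <- q$values[grid_origin(g)["ix"], ]
  during <- g$t >= 4 & g$t <= 12
  expect_lt(min(qc[during]), 0)                 # initial decrease
  relax <- g$t > 12 & g$t <= 40
  expect_gt(max(qc[relax]), min(qc[during]))    # delayed rise past the dip
})

test_that("BOLD observation equation is linear with the expected signs", {
  p <- hemo_params()
  g <- st_grid(dx = 0.5, dt = 0.5, nx = 8, nt = 8)
  xi <- matrix(rnorm(64), 8, 8); q <- matrix(rnorm(64), 8, 8)
  y0 <- bold_signal(array(0, c(8, 8)), array(0, c(8, 8)), p, grid = g)
  expect_true(all(y0$values == 0))
  y1 <- bold_signal(xi, q, p, grid = g)
  y2 <- bold_signal(2 * xi, 2 * q, p, grid = g)
  expect_equal(y2$values, 2 * y1$values)
  # isolated dHb decrease raises the signal
  yq <- bold_signal(array(0, c(8, 8)), array(-0.1, c(8, 8)), p, grid = g)
  expect_true(all(yq$values > 0))
  # shape mismatch
  expect_error(bold_signal(matrix(0, 4, 4), matrix(0, 8, 8), p, grid = g),
               "shape")
})

test_that("spatial integral of the stHRF equals the k = 0 temporal response", {
  wp <- wave_params(3, 0.8, a_F = 1)
  g <- st_grid(dx = 0.5, dt = 0.125, nx = 64, nt = 256)
  y <- compute_sthrf(wp, g)
  integ <- colSums(y$values) * g$dx
  # k = 0 (purely temporal) response to the same unit-integral impulse
  gt <- exp(-g$t^2 / (2 * g$dt^2)); gt <- gt / (sum(gt) * g$dt)
  tf <- assemble_transfer_functions(wp, g)
  y0 <- Re(stats::fft(tf$T_yz[1, ] * stats::fft(gt), inverse = TRUE)) / g$nt
  expect_equal(integ, y0, tolerance = 1e-10)
})
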
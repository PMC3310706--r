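# phase fronts and regression estimators on analytically known fields

plane_wave <- function(v, f0 = 0.05, K = 0, dt = 0.25, pitch = 0.75,
                       x_max = 9, T = 80) {
  t <- seq(0, T - dt, by = dt)
  x <- seq(-x_max, x_max, by = pitch)
  y <- outer(x, t, function(xx, tt)
    exp(-K * abs(xx)) * cos(2 * pi * f0 * (tt - abs(xx) / v)))
  list(y = y, t = t, x = x, f0 = f0)
}

test_that("phase fronts of a traveling sinusoid are exact lines", {
  pw <- plane_wave(v = 2)
  pf <- analytic_phase(pw$y, t = pw$t, x = pw$x, f0 = pw$f0)
  fr <- extract_phase_front(pf, x_min = 1, x_max = 9)
  for (side in c("F", "P")) {
    f <- fr[[side]]
    expect_null(f$flag)
    slope <- coef(lm(f$t ~ f$x))[2]
    expect_equal(unname(slope), 1 / 2, tolerance = 1e-3)
    sp <- fit_wave_speed(f, trim = FALSE)
    expect_equal(sp$v, 2, tolerance = 1e-3)
    expect_lt(sp$sd, 1e-3)
    # pure sinusoid: no amplitude decay along the front
    dc <- fit_decay(f, trim = FALSE)
    expect_equal(dc$Gamma_t, 0, tolerance = 1e-3)
    expect_equal(dc$K, 0, tolerance = 1e-3)
  }
})

test_that("decaying traveling waves give consistent K, Gamma_t and v", {
  pw <- plane_wave(v = 2.5, K = 0.3)
  pf <- analytic_phase(pw$y, t = pw$t, x = pw$x, f0 = pw$f0)
  fr <- extract_phase_front(pf, x_min = 1, x_max = 9)
  dc <- fit_decay(fr$F, trim = FALSE)
  sp <- fit_wave_speed(fr$F, trim = FALSE)
  expect_equal(dc$K, 0.3, tolerance = 0.01)
  expect_equal(dc$Gamma_t, -0.3 * 2.5, tolerance = 0.02)
  expect_equal(abs(dc$Gamma_t) / (dc$K * sp$v), 1, tolerance = 0.02)
})

test_that("speed fits propagate uncertainty and flag unphysical fronts", {
  # exact line t = 1 + |x| / 3
  xs <- seq(1.5, 6, by = 0.75)
  fr <- structure(list(x = xs, t = 1 + xs / 3, amplitude = exp(-0.2 * xs),
                       side = "F", flag = NULL), class = "wave_front")
  sp <- fit_wave_speed(fr, trim = FALSE)
  expect_equal(sp$v, 3, tolerance = 1e-12)
  expect_equal(sp$sd, 0, tolerance = 1e-9)
  # exponential decay in time with rate 0.5
  fr2 <- structure(list(x = xs, t = 1 + xs / 3,
                        amplitude = 2 * exp(-0.5 * (1 + xs / 3)),
                        side = "F", flag = NULL), class = "wave_front")
  dc <- fit_decay(fr2, trim = FALSE)
  expect_equal(dc$Gamma_t, -0.5, tolerance = 1e-10)
  # a backward-sloping front is unphysical
  fr3 <- structure(list(x = xs, t = 5 - xs / 3, amplitude = exp(-0.2 * xs),
                        side = "P", flag = NULL), class = "wave_front")
  expect_identical(fit_wave_speed(fr3)$flag, "unphysical")
  # non-positive amplitudes are dropped with a message
  fr4 <- fr2; fr4$amplitude[3] <- 0
  expect_message(dc4 <- fit_decay(fr4, trim = FALSE), "non-positive")
  expect_equal(dc4$Gamma_t, -0.5, tolerance = 1e-10)
})

test_that("1-sd intervals from the speed fit have near-nominal coverage", {
  set.seed(31)
  xs <- seq(1.5, 7.5, by = 0.75)
  cover <- 0
  for (i in 1:20) {
    fr <- structure(list(x = xs, t = 2 + xs / 3 + rnorm(length(xs), sd = 0.15),
                         amplitude = rep(1, length(xs)), side = "F",
                         flag = NULL), class = "wave_front")
    sp <- fit_wave_speed(fr, trim = FALSE)
    cover <- cover + (abs(sp$v - 3) <= sp$sd)
  }
  expect_gte(cover, 9)    # binomial(20, 0.68) comfortably above chance
  expect_lte(cover, 20)
})

test_that("FWHM estimation matches closed forms and flags multi-peak profiles", {
  dt <- 0.25; t <- seq(0, 80 - dt, by = dt); f0 <- 0.05
  x <- seq(-10, 10, by = 0.25)
  y <- outer(exp(-x^2 / (2 * 2^2)), cos(2 * pi * f0 * t))
  fw <- estimate_fwhm(y, t = t, x = x, f0 = f0)
  expect_equal(fw$fwhm, 2 * sqrt(2 * log(2)) * 2, tolerance = 0.02)
  expect_null(fw$flag)
  fw2 <- estimate_fwhm(5 * y, t = t, x = x, f0 = f0)
  expect_equal(fw2$fwhm, fw$fwhm)    # scale invariance
  y2 <- outer(exp(-(x - 5)^2 / 2) + 0.8 * exp(-(x + 5)^2 / 2),
              cos(2 * pi * f0 * t))
  fw3 <- estimate_fwhm(y2, t = t, x = x, f0 = f0)
  expect_identical(fw3$flag, "multipeak")
})
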
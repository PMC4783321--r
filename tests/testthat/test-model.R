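test_that("model constructor enforces positivity of D, tau, alpha", {
  expect_s3_class(kiss_model(1, 0, 2), "kiss_model")
  expect_error(kiss_model(-1, 1, 1), "positive diffusion")
  expect_error(kiss_model(1, -0.1, 1), "non-negative growth")
  expect_error(kiss_model(1, 1, 0), "alpha > 0")
})

test_that("critical patch size is pi*sqrt(D/tau), undefined for tau = 0", {
  expect_equal(critical_length(kiss_model(1, 1)), pi)
  expect_equal(critical_length(kiss_model(4, 1)), 2 * pi)
  expect_equal(critical_length(kiss_model(1, 4)), pi / 2)
  expect_error(critical_length(kiss_model(1, 0)), "tau = 0")
})

test_that("sine coefficients recover orthogonal modes and match dense quadrature", {
  a <- fourier_sine_coefficients(function(x) sin(pi * x), 1, 4)
  expect_equal(a, c(1, 0, 0, 0), tolerance = 1e-10)
  a2 <- fourier_sine_coefficients(function(x) sin(2 * pi * x), 1, 4)
  expect_equal(a2, c(0, 1, 0, 0), tolerance = 1e-10)

  # u0 = x(1-x): a_1 from a >= 1e5-point trapezoid oracle, and closed form 8/pi^3
  xs <- seq(0, 1, length.out = 200001)
  fs <- xs * (1 - xs) * sin(pi * xs)
  oracle <- 2 * (sum(fs) - (fs[1] + fs[length(fs)]) / 2) * (1 / 200000)
  a3 <- fourier_sine_coefficients(function(x) x * (1 - x), 1, 1)
  expect_equal(a3[1], oracle, tolerance = 1e-9)
  expect_equal(a3[1], 8 / pi^3, tolerance = 1e-9)

  expect_error(
    fourier_sine_coefficients(function(x) ifelse(x > 0.5, NaN, 1), 1, 1),
    "non-finite")
})

test_that("linear series reconstructs u0, freezes the critical mode, grows supercritically", {
  m <- kiss_model(1, 1)
  u0 <- function(x) sin(pi * x) + 0.5 * sin(3 * pi * x)
  a <- fourier_sine_coefficients(u0, 1, 8)
  sol <- linear_kiss_solution(m, 1, a)
  xs <- seq(0, 1, length.out = 41)
  expect_equal(linear_kiss_series(xs, 0, sol), u0(xs), tolerance = 1e-9)
  expect_error(linear_kiss_series(0.5, -1, sol), "t must be")

  # single mode at l = pi*sqrt(D/tau): growth exponent exactly zero
  lc <- critical_length(m)
  stat <- linear_kiss_solution(m, lc, 1)
  for (t in c(0, 0.7, 5, 40)) {
    expect_equal(linear_kiss_series(lc / 2, t, stat), 1, tolerance = 1e-14)
  }

  # D = 1, tau = 1, l = 2*pi: exponent tau - D pi^2/l^2 = 3/4
  grow <- linear_kiss_solution(m, 2 * pi, 1)
  expect_equal(linear_kiss_series(pi, 1, grow), exp(0.75), tolerance = 1e-12)
})

test_that("subcritical single-mode amplitude decreases monotonically in t", {
  m <- kiss_model(2, 0.5, 1)
  l <- 0.8 * critical_length(m)
  sol <- linear_kiss_solution(m, l, 1)
  ts <- seq(0, 3, by = 0.25)
  peaks <- vapply(ts, function(t) max(abs(linear_kiss_series(
    seq(0, l, length.out = 101), t, sol))), numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("heat kernel has the printed peak, is even, and carries unit mass", {
  # peak 1/sqrt(4 pi D t): at D = 1, t = 1/(4 pi) the peak is exactly 1
  expect_equal(heat_kernel_solution(0, 1 / (4 * pi), 1), 1)
  xs <- seq(0.1, 5, by = 0.3)
  expect_equal(heat_kernel_solution(xs, 0.7, 2), heat_kernel_solution(-xs, 0.7, 2))
  for (t in c(0.3, 1, 4)) {
    xq <- seq(-20, 20, length.out = 80001)
    u <- heat_kernel_solution(xq, t, 1)
    mass <- (sum(u) - (u[1] + u[length(u)]) / 2) * (40 / 80000)
    expect_equal(mass, 1, tolerance = 1e-8)
  }
  expect_error(heat_kernel_solution(0, 0, 1), "t > 0")
})

test_that("step-front solution reduces to erf identities", {
  expect_equal(step_front_solution(0, 1, 1), 0.5)
  expect_lt(step_front_solution(50, 1, 1), 1e-12)
  # x = -sqrt(4 D t): (1 + erf(1))/2, cross-checked by dense quadrature
  v <- step_front_solution(-sqrt(4 * 0.5 * 2), 2, 0.5)
  xi <- seq(-1, 12, length.out = 400001)
  f <- exp(-xi^2)
  quad <- (sum(f) - (f[1] + f[length(f)]) / 2) * (13 / 400000) / sqrt(pi)
  expect_equal(v, quad, tolerance = 1e-9)
  expect_equal(v, (1 + (2 * pnorm(sqrt(2)) - 1)) / 2, tolerance = 1e-12)
  expect_error(step_front_solution(0, -1, 1), "t > 0")
})

test_that("initial-condition catalog matches its defining formulas", {
  expect_equal(catalog_ic("sin2pix")$fun(0.25), 1)
  expect_equal(catalog_ic("sinc_radial")$fun(0, 0), 1)
  r <- sqrt(1.3^2 + 0.4^2)
  expect_equal(catalog_ic("sinc_radial")$fun(1.3, 0.4), sin(r) / r)
  expect_equal(catalog_ic("exp_trig_sum")$fun(0, 0), exp(0.1))
  expect_equal(catalog_ic("coscos_exp")$fun(1, 2),
               cos(1) * cos(2) * exp(-sqrt(5) / 4))
  expect_equal(catalog_ic("sin_radial")$fun(pi, 0), sin(1))
  expect_error(catalog_ic("nope"), "catalog")
})
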
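test_that("amplification factor has the pure-linear and RK4 limits", {
  for (y in c(-4, -1.2, -0.3, 0)) {
    expect_equal(amplification_factor(0, y), exp(y), tolerance = 1e-14)
  }
  rk4 <- function(x) 1 + x + x^2 / 2 + x^3 / 6 + x^4 / 24
  for (x in c(-2.5, -1, -0.1, 0.3)) {
    expect_equal(amplification_factor(x, 0), rk4(x), tolerance = 1e-13)
  }
})

test_that("amplification factor is conjugate symmetric", {
  set.seed(7)
  for (i in 1:25) {
    x <- complex(real = runif(1, -3, 1), imaginary = runif(1, -3, 3))
    y <- complex(real = runif(1, -3, 0), imaginary = runif(1, -1, 1))
    expect_equal(amplification_factor(Conj(x), Conj(y)),
                 Conj(amplification_factor(x, y)), tolerance = 1e-12)
  }
})

test_that("exact bivariate expansion carries the known coefficient table", {
  s <- series_coefficients(3)
  expected_num <- rbind(
    c(1, 1, 1, 1),          # g0 = e^y
    c(1, 1, 1, 1),          # g1 = 1 + y + y^2/2 + y^3/6
    c(1, 1, 1, 247),        # g2
    c(1, 1, 61, 1),         # g3
    c(1, 1, 7, 19))         # g4
  expected_den <- rbind(
    c(1, 1, 2, 6),
    c(1, 1, 2, 6),
    c(2, 2, 4, 2880),
    c(6, 6, 720, 36),
    c(24, 32, 640, 11520))
  expect_identical(unname(s$num), expected_num)
  expect_identical(unname(s$den), expected_den)
  # y = 0 column is the RK4 polynomial
  expect_equal(s$value[, 1], c(1, 1, 1 / 2, 1 / 6, 1 / 24))
})

test_that("exact expansion agrees with a numeric finite-difference oracle", {
  # Richardson-extrapolated central differences of r(x, y) in x at y fixed,
  # then in y, entirely independent of the rational-series code
  s <- series_coefficients(3)
  num_gi <- function(i, y) {
    h <- 0.01
    xs <- h * (-4:4)
    rv <- vapply(xs, function(x) Re(amplification_factor(x, y)), numeric(1))
    fit <- lm(rv ~ poly(xs, 6, raw = TRUE))
    unname(coef(fit)[i + 1])
  }
  for (i in 2:4) {
    ys <- 0.02 * (-4:4)
    gi <- vapply(ys, function(y) num_gi(i, y), numeric(1))
    fit <- lm(gi ~ poly(ys, 5, raw = TRUE))
    for (j in 0:3) {
      # double-precision fits resolve the corner coefficients to ~1%
      tol <- if (i + j >= 6) 0.05 else 1e-3
      expect_equal(unname(coef(fit)[j + 1]), s$value[i + 1, j + 1],
                   tolerance = tol)
    }
  }
})

test_that("truncated expansion is consistent with exactness to fifth order", {
  s <- series_coefficients(6)
  eval_r <- function(x, y) {
    gy <- s$value %*% y^(0:6)
    sum(gy * x^(0:4))
  }
  res <- vapply(c(0.2, 0.1, 0.05, 0.025), function(t)
    abs(eval_r(-t, -t) - exp(-2 * t)), numeric(1))
  ratios <- res[-4] / res[-1]
  expect_true(all(ratios > 20))  # ~2^5 = 32 per halving
})

test_that("stability boundaries satisfy |r| = 1 and grow with |y|", {
  ys <- c(0, -3.5, -5, -7, -9, -11)
  areas <- numeric(length(ys))
  for (i in seq_along(ys)) {
    curve <- trace_boundary(ys[i], 256)
    pts <- complex(real = curve$re, imaginary = curve$im)
    resid <- vapply(pts, function(p)
      abs(Mod(amplification_factor(p, ys[i])) - 1), numeric(1))
    expect_lt(max(resid), 1e-10)
    expect_lt(Mod(pts[1] - pts[length(pts)]), 1e-6)  # closed curve
    # symmetry about the real axis: the conjugate of every sampled point lies
    # on the curve (within the local sample spacing)
    spacing <- max(Mod(diff(pts)))
    sub <- pts[seq(1, length(pts), by = 16)]
    dmin <- vapply(Conj(sub), function(p) min(Mod(pts - p)), numeric(1))
    expect_lt(max(dmin), spacing)
    areas[i] <- attr(curve, "area")
  }
  expect_true(all(diff(areas) > 0))
})

test_that("the y = 0 boundary is the classical RK4 region", {
  curve <- trace_boundary(0, 256)
  # leftmost real-axis crossing by brute-force bisection on |r(x,0)| = 1
  f <- function(x) abs(1 + x + x^2 / 2 + x^3 / 6 + x^4 / 24) - 1
  lo <- -3; hi <- -2.5
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(min(curve$re), (lo + hi) / 2, tolerance = 1e-4)
  expect_equal(min(curve$re), -2.7853, tolerance = 1e-4)
})
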
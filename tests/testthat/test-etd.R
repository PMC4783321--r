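test_that("phi weights attain their removable-singularity limits at z = 0", {
  w <- phi_weights(0, h = 2)
  expect_equal(w$E, 1); expect_equal(w$E2, 1)
  expect_equal(w$Q, 1, tolerance = 1e-14)          # h/2
  expect_equal(w$Wu, 2 / 6, tolerance = 1e-14)
  expect_equal(w$Wab, 2 / 6, tolerance = 1e-14)
  expect_equal(w$Wc, 2 / 6, tolerance = 1e-14)
})

test_that("contour and direct phi evaluations agree on well-resolved modes", {
  for (z in c(-10, -2, -0.75)) {
    direct <- phi_weights(z, 1, cutoff = 0.5)
    contour <- phi_weights(z, 1, contour_points = 64L, cutoff = 1e6)
    for (nm in c("Q", "Wu", "Wab", "Wc")) {
      expect_lt(abs(direct[[nm]] - contour[[nm]]) / abs(direct[[nm]]), 1e-12)
    }
  }
})

test_that("phi weights match extended-precision series on small |z|", {
  # reference values from the Taylor series of each weight, computed with
  # exact rational coefficients at |z| <= 1 (series truncated far below 1e-20)
  series_eval <- function(coefs, z) sum(coefs * z^(seq_along(coefs) - 1))
  # (e^{z/2}-1)/z = sum_{k>=1} z^{k-1}/(2^k k!)
  qc <- 1 / (2^(1:25) * factorial(1:25))
  for (z in c(-1, -0.3, 0.12, 0.49)) {
    w <- phi_weights(z, 1)
    expect_lt(abs(w$Q - series_eval(qc, z)) / abs(w$Q), 1e-12)
  }
})

test_that("scalar bracket weight reproduces the closed-form value at z = -1", {
  w <- phi_weights(-1, 1)
  expect_equal(w$E, exp(-1))
  # [-4 - (-1) + e^{-1}(4 + 3 + 1)]/(-1)^3 = 3 - 8/e
  expect_equal(w$Wu, 3 - 8 / exp(1), tolerance = 1e-13)
})

test_that("ETDRK4 is exact for F = 0 and reproduces e^{Lh} per step", {
  sys <- semilinear_system(c(-3, -1, 0, 0.5), function(u, t) 0 * u)
  co <- etdrk4_coefficients(c(-3, -1, 0, 0.5), 0.25)
  u <- c(1, 2, 3, 4)
  expect_equal(etdrk4_step(sys, u, 0, 0.25, co),
               exp(0.25 * c(-3, -1, 0, 0.5)) * u, tolerance = 1e-15)
})

test_that("multistep schemes with F = 0 also reduce to exp(Lh)", {
  z <- c(-2, -0.4)
  sys <- semilinear_system(z, function(u, t) 0 * u)
  for (scheme in c("ETDM4", "ETDM5", "ETDM6", "ETDADAMS4")) {
    co <- etd_multistep_coefficients(z, 0.1, scheme)
    p <- scheme_spec(scheme)$order
    hist <- rep(list(c(0, 0)), p)
    expect_equal(etd_multistep_step(sys, hist, c(1, 1), 0, 0.1, co),
                 exp(0.1 * z), tolerance = 1e-14)
  }
  co <- etd_multistep_coefficients(z, 0.1, "ETDM4")
  expect_error(etd_multistep_step(sys, list(c(0, 0)), c(1, 1), 0, 0.1, co),
               "startup")
})

test_that("ETDRK4 converges at fourth order on the scalar blow-up oracle", {
  fx <- make_fixture("scalar_ode")
  errs <- vapply(c(1 / 20, 1 / 40, 1 / 80), function(h)
    abs(step_to(fx$system, fx$u0, 0.5, h) - fx$exact(0.5)), numeric(1))
  ratios <- errs[-3] / errs[-1]
  expect_true(all(ratios > 12 & ratios < 20))
})

test_that("exponential multistep comparators attain their design orders", {
  fx <- make_fixture("scalar_ode")
  hs <- 1 / c(32, 64, 128, 256)
  target <- c(ETDM4 = 4, ETDADAMS4 = 4, ETDM5 = 5, ETDM6 = 6)
  for (scheme in names(target)) {
    errs <- vapply(hs, function(h)
      abs(step_to(fx$system, fx$u0, 0.5, h, scheme) - fx$exact(0.5)),
      numeric(1))
    expect_equal(order_slope(hs, errs), target[[scheme]], tolerance = 0.45)
  }
  # the two order-4 variants are distinct code paths but agree closely
  e1 <- abs(step_to(fx$system, fx$u0, 0.5, 1 / 64, "ETDM4") - fx$exact(0.5))
  e2 <- abs(step_to(fx$system, fx$u0, 0.5, 1 / 64, "ETDADAMS4") - fx$exact(0.5))
  expect_equal(e1, e2, tolerance = 1e-6)
})

test_that("tensor coefficients act as the scalar weight of the summed eigenvalues", {
  g <- build_grid(grid_spec(2, 0, 1, 9))
  L <- fd4_laplacian_2d(g, D = 0.3)
  h <- 0.01
  co <- etdrk4_coefficients(L, h)
  ex <- eigen(L$Ax, symmetric = TRUE)
  ey <- eigen(L$Ay, symmetric = TRUE)
  i <- 2; j <- 5
  U <- outer(ex$vectors[, i], ey$vectors[, j])
  z <- h * (ex$values[i] + ey$values[j])
  wref <- phi_weights(z, h)
  expect_equal(kissrd:::.etd_apply(co, "Wu", U), wref$Wu * U, tolerance = 1e-11)
  expect_equal(kissrd:::.etd_apply(co, "E", U), exp(z) * U, tolerance = 1e-11)
})

test_that("ETDRK4 propagates a linear sine mode by its exact growth factor", {
  m <- kiss_model(1, 1, 1)
  g <- build_grid(grid_spec(1, 0, 1, 101, "dirichlet0"))
  sys <- assemble_system(m, g, "dst")   # spectral: spatial mode is exact
  h <- 0.02
  co <- etdrk4_coefficients(sys$L, h)
  u <- sin(pi * g$x[2:100])
  u1 <- etdrk4_step(sys, u, 0, h, co)
  factor <- exp((1 - pi^2) * h)
  # per-step defect is O(tau*h * ((tau + D pi^2) h)^4) ~ 4e-8 at h = 0.02
  expect_equal(u1 / u, rep(factor, 99), tolerance = 1e-6)
  # and shrinks ~16x per step halving
  co2 <- etdrk4_coefficients(sys$L, h / 2)
  u2 <- etdrk4_step(sys, u, 0, h / 2, co2)
  d1 <- max(abs(u1 / u - factor))
  d2 <- max(abs(u2 / u - exp((1 - pi^2) * h / 2)))
  expect_gt(d1 / d2, 20)  # one power of h from the x factor joins the h^4
})

test_that("integrator respects the critical patch threshold in both directions", {
  m <- kiss_model(1, 1, 1)
  run_l <- function(l) {
    g <- build_grid(grid_spec(1, 0, l, 41))
    sys <- assemble_system(m, g)
    res <- integrate_kiss(sys, sin(pi * g$x / l), T = 2, k = 0.01)
    max(abs(res$final_state)) / max(abs(sin(pi * g$x[2:40] / l)))
  }
  expect_lt(run_l(0.8 * pi), 1)   # subcritical: decay
  expect_gt(run_l(1.3 * pi), 1)   # supercritical: growth
})

test_that("integrate rejects off-grid snapshots and partial final steps", {
  m <- kiss_model(1, 0, 1)
  g <- build_grid(grid_spec(1, 0, 1, 21))
  sys <- assemble_system(m, g)
  expect_error(integrate_kiss(sys, sin(pi * g$x), T = 1.005, k = 0.01),
               "not an integer")
  expect_error(integrate_kiss(sys, sin(pi * g$x), T = 1, k = 0.01,
                              snapshot_times = 0.0153), "step grid")
})

test_that("finite-time blow-up is flagged with the last valid time retained", {
  fx <- make_fixture("scalar_ode")   # u' = u^2 blows up at t = 1
  res <- integrate_kiss(fx$system, 1, T = 2, k = 0.01,
                        blowup_threshold = 1e6)
  expect_true(res$blowup$flag)
  expect_lt(res$blowup$last_valid_time, 1.05)
  expect_gt(res$blowup$last_valid_time, 0.9)
  expect_true(all(is.finite(res$diagnostics$max)))
})

test_that("simulation diagnostics are reproducible bit-for-bit", {
  m <- kiss_model(0.5, 0.5, 2)
  g <- build_grid(grid_spec(1, -1, 1, 31))
  sys <- assemble_system(m, g)
  r1 <- integrate_kiss(sys, catalog_ic("sin2pix"), T = 0.5, k = 0.01)
  r2 <- integrate_kiss(sys, catalog_ic("sin2pix"), T = 0.5, k = 0.01)
  expect_identical(r1$diagnostics, r2$diagnostics)
  expect_identical(r1$final_state, r2$final_state)
})
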
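test_that("grid construction follows the stated spacing conventions", {
  g <- build_grid(grid_spec(1, -1, 1, 201))
  expect_equal(g$h, 0.01)
  expect_equal(g$x[1], -1)
  expect_equal(g$x[201], 1)
  expect_error(grid_spec(1, 0, 1, 5), "N >= 7")
  g2 <- build_grid(grid_spec(2, -10, 10, 101))
  expect_equal(g2$h, c(0.2, 0.2))
  expect_length(g2$x, 101)
  expect_length(g2$y, 101)
  # periodic: right endpoint identified with the left
  gp <- build_grid(grid_spec(1, -pi, pi, 64, "periodic"))
  expect_equal(gp$h, 2 * pi / 64)
  expect_equal(gp$x[1], -pi)
  expect_lt(max(gp$x), pi)
  expect_error(grid_spec(1, 0, 1, 9, "periodic"), "even")
})

test_that("FD4 operator is exact on quartics-and-below and fourth order on sine", {
  g <- build_grid(grid_spec(1, -1, 1, 21))
  L <- fd4_laplacian_1d(g)
  u <- g$x[2:20]^2
  expect_equal(apply_operator(L, u)[3:15], rep(2, 13), tolerance = 1e-10)
  expect_equal(sum(c(-1, 16, -30, 16, -1)), 0)

  err_at <- function(N) {
    gg <- build_grid(grid_spec(1, 0, 1, N))
    xi <- gg$x[2:(N - 1)]
    max(abs(apply_operator(fd4_laplacian_1d(gg), sin(pi * xi)) +
              pi^2 * sin(pi * xi)))
  }
  ratio <- err_at(101) / err_at(201)
  expect_gt(ratio, 13); expect_lt(ratio, 19)
})

test_that("FD4 operator equals the brute-force dense construction entrywise", {
  for (N in c(11, 27, 51)) {
    g <- build_grid(grid_spec(1, -2, 3, N))
    L <- fd4_laplacian_1d(g, D = 0.7)
    expect_equal(L$mat, brute_force_fd4(N, g$h, 0.7), tolerance = 1e-14)
  }
})

test_that("FD4 Dirichlet spectrum is real and negative", {
  g <- build_grid(grid_spec(1, 0, 1, 21))
  ev <- eigen(fd4_laplacian_1d(g)$mat, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev < 0))
})

test_that("2-D tensor operator obeys the Kronecker-sum identity without materializing it", {
  g <- build_grid(grid_spec(2, -10, 10, 21))
  L <- fd4_laplacian_2d(g)
  xi <- g$x[2:20]; yi <- g$y[2:20]
  U <- outer(xi, yi, function(x, y) x^2 + y^2)
  expect_equal(apply_operator(L, U)[5:15, 5:15],
               matrix(4, 11, 11), tolerance = 1e-9)
  # L(f x g) = (A f) g' + f (B g)' nodewise
  f <- sin(xi); gg <- cos(yi)
  lhs <- apply_operator(L, outer(f, gg))
  rhs <- outer(drop(L$Ax %*% f), gg) + outer(f, drop(L$Ay %*% gg))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("spectral symbol is exact on trigonometric polynomials and nonpositive", {
  g <- build_grid(grid_spec(1, -pi, pi, 64, "periodic"))
  Ls <- spectral_symbol(g, D = 3)
  expect_true(all(Ls$symbol <= 0))
  expect_equal(apply_operator(Ls, rep(1, 64)), rep(0, 64), tolerance = 1e-13)
  u <- sin(g$x) + 0.2 * cos(5 * g$x)
  expect_equal(apply_operator(Ls, u),
               -3 * (sin(g$x) + 5 * 0.2 * 5 * cos(5 * g$x)),
               tolerance = 1e-11)
  expect_error(spectral_symbol(build_grid(grid_spec(1, 0, 1, 33))),
               "sine-transform")
})

test_that("sine-transform path diagonalizes the Dirichlet Laplacian", {
  g <- build_grid(grid_spec(1, 0, 1, 33))
  m <- kiss_model(1, 0, 1)
  sys <- assemble_system(m, g, disc = "dst")
  xi <- g$x[2:32]
  u <- sin(2 * pi * xi)
  expect_equal(apply_operator(sys$L, u), -(2 * pi)^2 * u, tolerance = 1e-10)
  expect_error(assemble_system(m, build_grid(grid_spec(1, 0, 1, 32, "periodic")),
                               disc = "dst"), "dirichlet0")
})

test_that("assembled nonlinearity is tau * u^alpha with the stated guards", {
  g <- build_grid(grid_spec(1, 0, 1, 9))
  sys <- assemble_system(kiss_model(1, 0.5, 2), g)
  expect_equal(sys$F(c(-2, 0, 3), 0), 0.5 * c(4, 0, 9))
  expect_equal(sys$F(rep(0, 7), 1), rep(0, 7))
  sys0 <- assemble_system(kiss_model(1, 0, 2), g)
  expect_equal(sys0$F(c(1, 2), 0), c(0, 0))
  # non-integer alpha: real signed power
  sysf <- assemble_system(kiss_model(1, 1, 1.5), g)
  expect_equal(sysf$F(c(-4, 4), 0), c(-8, 8))
})

test_that("pure-diffusion Dirichlet runs dissipate the discrete energy", {
  m <- kiss_model(1, 0, 1)
  for (disc in c("fd4", "dst")) {
    g <- build_grid(grid_spec(1, 0, 1, 41))
    sys <- assemble_system(m, g, disc)
    co <- etdrk4_coefficients(sys$L, 0.002)
    u <- sin(pi * g$x[2:40]) + 0.4 * sin(5 * pi * g$x[2:40])
    en <- sum(u^2)
    for (n in 1:40) {
      u <- etdrk4_step(sys, u, 0, 0.002, co)
      en2 <- sum(u^2)
      expect_lt(en2, en)
      en <- en2
    }
  }
})
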
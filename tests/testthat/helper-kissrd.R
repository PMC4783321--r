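# Brute-force construction of the 1-D FD4 Dirichlet operator: loop over the
# stencil with explicit ghost-node substitution, independent of the package's
# assembly code.
brute_force_fd4 <- function(N, h, D = 1) {
  w <- D * c(-1, 16, -30, 16, -1) / (12 * h^2)
  n <- N - 2
  A <- matrix(0, n, n)
  for (i in 1:n) {
    for (s in -2:2) {
      j <- i + s
      val <- w[s + 3]
      if (j >= 1 && j <= n) {
        A[i, j] <- A[i, j] + val
      } else if (j == 0 || j == n + 1) {
        # wall node, u = 0: contributes nothing
      } else if (j == -1) {
        A[i, 1] <- A[i, 1] - val        # u_{-1} = -u_1
      } else if (j == n + 2) {
        A[i, n] <- A[i, n] - val        # mirrored ghost on the right
      }
    }
  }
  A
}

# integrate a scalar/vector semilinear system with any scheme, returning the
# final state (test-side driver, independent of integrate_kiss bookkeeping)
step_to <- function(system, u0, T, h, scheme = "ETDRK4") {
  spec <- scheme_spec(scheme)
  rk <- etdrk4_coefficients(system$L, h)
  ms <- if (spec$multistep) etd_multistep_coefficients(system$L, h, scheme)
  u <- u0
  Fh <- list(system$F(u, 0))
  for (n in seq_len(round(T / h))) {
    t <- (n - 1) * h
    u <- if (spec$multistep && n > spec$startup_steps)
      etd_multistep_step(system, Fh, u, t, h, ms)
    else etdrk4_step(system, u, t, h, rk)
    Fh <- c(list(system$F(u, n * h)), Fh)
    if (length(Fh) > spec$order) Fh <- Fh[seq_len(spec$order)]
  }
  u
}

# log-log least-squares slope of errors against step sizes
order_slope <- function(hs, errs) {
  -unname(coef(lm(log(errs) ~ log(1 / hs)))[2])
}
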
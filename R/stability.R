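#' Linear stability analysis of the ETDRK4 scheme
#'
#' The scalar two-parameter test problem u' = g u + lambda u splits the right
#' side into a part treated exactly through the exponential (g) and a part
#' treated as the "nonlinearity" (lambda u). One ETDRK4 step maps u_n to
#' r(x, y) u_n with x = lambda*h and y = g*h; the stability region for fixed y
#' is the set of x with |r| <= 1.
#'
#' @name stability
NULL

# Scalar ETDRK4 bracket weights at z = g*h, written out independently of the
# integrator module. Near z = 0 the closed forms suffer catastrophic
# cancellation, so they are evaluated as the mean over a contour of `M` points
# on a unit circle centred at z (Kassam-Trefethen device). The same evaluation
# convention (M = 32 points, direct formula for |z| >= 0.5) is used throughout
# the package so both code paths agree to the last unit in the last place.
.stab_weights <- function(y, M = 32L, cutoff = 0.5) {
  f <- function(z) {
    list(Q  = (exp(z / 2) - 1) / z,
         Wu = (-4 - z + exp(z) * (4 - 3 * z + z^2)) / z^3,
         Wab = (2 + z + exp(z) * (-2 + z)) / z^3,
         Wc = (-4 - 3 * z - z^2 + exp(z) * (4 - z)) / z^3)
  }
  if (Mod(y) >= cutoff) {
    w <- f(y)
  } else {
    zs <- y + exp(2i * pi * (seq_len(M) - 0.5) / M)
    w <- lapply(f(zs), mean)
    if (is.numeric(y) || Im(y) == 0) w <- lapply(w, Re)
  }
  w$E <- exp(y)
  w$E2 <- exp(y / 2)
  w
}

#' ETDRK4 amplification factor r(x, y)
#'
#' Runs the ETDRK4 stage recurrence on the scalar problem u' = g u + lambda u
#' with u_n = 1 and returns u_{n+1} = r(x, y), where x = lambda*h is the
#' increment treated through the phi-weights and y = g*h the increment treated
#' exactly. r is an exact quartic polynomial in x whose coefficients are entire
#' functions of y; `r(0, y) = exp(y)` and `r(x, 0)` is the classical RK4
#' stability polynomial 1 + x + x^2/2 + x^3/6 + x^4/24.
#'
#' @param x complex or numeric scalar/vector, the "nonlinear" increment lambda*h.
#' @param y complex or numeric scalar, the exactly-integrated increment g*h.
#' @return the amplification factor(s), complex if any input is complex.
#' @examples
#' amplification_factor(0, -1)    # exp(-1)
#' amplification_factor(-1, 0)    # RK4 polynomial at -1
#' @export
amplification_factor <- function(x, y) {
  w <- .stab_weights(y)
  Fu <- x           # F(u_n) with u_n = 1
  a <- w$E2 + w$Q * Fu
  Fa <- x * a
  b <- w$E2 + w$Q * Fa
  Fb <- x * b
  cs <- w$E2 * a + w$Q * (2 * Fb - Fu)
  Fc <- x * cs
  w$E + w$Wu * Fu + 2 * (w$Wab * (Fa + Fb)) + w$Wc * Fc
}

# add polynomials given as ascending coefficient vectors, padding with zeros
.padd <- function(p, q) {
  n <- max(length(p), length(q))
  c(p, rep(0, n - length(p))) + c(q, rep(0, n - length(q)))
}

# quartic coefficients g_0(y)..g_4(y) of r(x,y) in x, exact in y (numeric)
.stab_poly_coef <- function(y) {
  w <- .stab_weights(y)
  # stage polynomials in x, ascending coefficient vectors
  a <- c(w$E2, w$Q)                         # E2 + Q x
  b <- c(w$E2, w$Q * a)                     # E2 + Q x a
  cc <- .padd(w$E2 * a, c(0, w$Q * .padd(2 * b, -1)))  # E2 a + Q x (2b - 1)
  inner <- .padd(.padd(w$Wu, 2 * w$Wab * .padd(a, b)), w$Wc * cc)
  .padd(w$E, c(0, inner))  # length 5: g0..g4
}

#' Exact bivariate Taylor expansion of the ETDRK4 amplification factor
#'
#' Expands r(x, y) = sum_i g_i(y) x^i about (0, 0) with exact rational
#' arithmetic, by propagating truncated rational power series in y through the
#' ETDRK4 stage recurrence (exp(y), exp(y/2) and the bracket weights are formal
#' series; no floating point is involved).
#'
#' @param max_y_order highest power of y retained in each g_i (>= 3).
#' @return an object of class `amplification_series` with fields `num`, `den`
#'   (5 x (max_y_order+1) integer-valued matrices, rows g_0..g_4, columns
#'   y^0..y^max_y_order) and `value = num/den`.
#' @examples
#' s <- series_coefficients(3)
#' s$value[3, 4] * 2880   # coefficient of x^2 y^3, times 2880
#' @export
series_coefficients <- function(max_y_order = 3) {
  if (max_y_order < 3) stop("max_y_order must be >= 3")
  K <- max_y_order + 3  # headroom for the /y^3 shift
  E  <- rs_exp(1, 1, K)
  E2 <- rs_exp(1, 2, K)
  one <- rs_const(1, 1, K)
  yser <- rs_new(c(0, 1, rep(0, K - 1)))
  y2 <- rs_mul(yser, yser)
  # Q = (e^{y/2} - 1)/y
  Q <- rs_shift_down(rs_add(E2, rs_scale(one, -1)), 1)
  # bracket weights / y^3
  Wu <- rs_shift_down(rs_add(rs_add(rs_const(-4, 1, K), rs_scale(yser, -1)),
                             rs_mul(E, rs_add(rs_add(rs_const(4, 1, K),
                                                     rs_scale(yser, -3)), y2))), 3)
  Wab <- rs_shift_down(rs_add(rs_add(rs_const(2, 1, K), yser),
                              rs_mul(E, rs_add(rs_const(-2, 1, K), yser))), 3)
  Wc <- rs_shift_down(rs_add(rs_add(rs_add(rs_const(-4, 1, K),
                                           rs_scale(yser, -3)),
                                    rs_scale(y2, -1)),
                             rs_mul(E, rs_add(rs_const(4, 1, K),
                                              rs_scale(yser, -1)))), 3)
  Kq <- rs_len(Q)  # series after shifting are shorter; align all to max_y_order+1
  trim <- function(s, L) list(n = s$n[seq_len(L)], d = s$d[seq_len(L)])
  L <- max_y_order + 1
  E <- trim(E, L); E2 <- trim(E2, L); Q <- trim(Q, L)
  Wu <- trim(Wu, L); Wab <- trim(Wab, L); Wc <- trim(Wc, L)
  zero <- rs_const(0, 1, max_y_order)

  # stage polynomials in x with series coefficients
  a <- list(E2, Q)
  b <- list(E2, rs_mul(Q, a[[1]]), rs_mul(Q, a[[2]]))
  # c = E2*a + Q*x*(2b - 1)
  twob <- lapply(b, rs_scale, num = 2)
  twob[[1]] <- rs_add(twob[[1]], rs_scale(trim(rs_const(1, 1, K), L), -1))
  cstage <- bp_add(c(lapply(a, function(s) rs_mul(E2, s)), list(zero, zero)),
                   c(list(zero), lapply(twob, function(s) rs_mul(Q, s))))
  # r = E + x*(Wu + 2*Wab*(a+b) + Wc*c)
  apb <- bp_add(c(a, list(zero)), b)                 # degree 2
  inner <- list(Wu, zero, zero, zero)
  inner <- bp_add(inner, c(lapply(apb, function(s) rs_mul(rs_scale(Wab, 2), s)),
                           list(zero)))
  inner <- bp_add(inner, lapply(cstage, function(s) rs_mul(Wc, s)))
  g <- c(list(E), inner)  # g0..g4

  num <- t(vapply(g, function(s) s$n, numeric(L)))
  den <- t(vapply(g, function(s) s$d, numeric(L)))
  structure(list(num = num, den = den, value = num / den,
                 max_y_order = max_y_order),
            class = "amplification_series")
}

#' @export
print.amplification_series <- function(x, ...) {
  cat("ETDRK4 amplification factor r(x,y) = sum_i g_i(y) x^i\n")
  cat("exact rational coefficients, y up to order", x$max_y_order, "\n")
  rownames(x$value) <- paste0("g", 0:4)
  colnames(x$value) <- paste0("y^", seq_len(ncol(x$value)) - 1)
  print(x$value, ...)
  invisible(x)
}

#' Trace the boundary of an ETDRK4 stability region
#'
#' For fixed real y <= 0 the boundary of the stability region in the complex
#' x plane is the locus |r(x, y)| = 1. Setting r = exp(i*theta) and sweeping
#' theta over \[0, 2*pi\] turns this into a family of quartics
#' sum_i g_i(y) x^i = exp(i*theta), solved by polynomial root finding with the
#' g_i evaluated from their closed forms (exact in y, not a truncated series).
#' The branch continuous in theta, seeded from the root nearest the origin at
#' theta = 0, is returned; each root is polished by Newton iteration so the
#' residual ||r| - 1| is at roundoff level.
#'
#' @param y real, y <= 0.
#' @param n_theta number of theta samples (>= 64); the curve closes on itself.
#' @return an object of class `stability_curve`: data frame with columns
#'   `theta`, `re`, `im` plus attributes `y` and `area` (enclosed area by the
#'   shoelace formula).
#' @export
trace_boundary <- function(y, n_theta = 512L) {
  stopifnot(is.numeric(y), length(y) == 1, y <= 0)
  if (n_theta < 64) stop("n_theta must be >= 64")
  g <- .stab_poly_coef(y)
  solve_at <- function(th, prev) {
    coef <- g
    coef[1] <- coef[1] - exp(1i * th)
    roots <- polyroot(coef)
    # Newton polish on the quartic
    for (it in 1:3) {
      p <- ((((g[5] * roots + g[4]) * roots + g[3]) * roots + g[2]) * roots +
              g[1]) - exp(1i * th)
      dp <- ((4 * g[5] * roots + 3 * g[4]) * roots + 2 * g[3]) * roots + g[2]
      roots <- roots - p / dp
    }
    roots[which.min(Mod(roots - prev))]
  }
  # The four root branches of the quartic permute as theta advances by 2*pi;
  # the closed boundary component through the starting root is recovered by
  # continuing over as many 2*pi sweeps as it takes to return (at most four).
  dtheta <- 2 * pi / n_theta
  x0 <- solve_at(0, 0 + 0i)
  theta <- 0
  xs <- x0
  prev <- x0
  max_steps <- 4L * n_theta + 1L
  for (m in seq_len(max_steps)) {
    th <- m * dtheta
    nxt <- solve_at(th, prev)
    step_len <- Mod(nxt - prev)
    if (step_len > 0.5 * max(1, Mod(nxt)))
      stop("branch discontinuity while tracing the boundary at theta = ",
           signif(th, 4))
    theta <- c(theta, th)
    xs <- c(xs, nxt)
    prev <- nxt
    if (m %% n_theta == 0 && Mod(nxt - x0) < 1e-8 * max(1, Mod(x0))) break
  }
  if (Mod(xs[length(xs)] - x0) > 1e-6 * max(1, Mod(x0)))
    stop("stability boundary failed to close after four theta sweeps")
  re <- Re(xs); im <- Im(xs)
  area <- abs(sum(re[-length(re)] * im[-1] - re[-1] * im[-length(im)])) / 2
  structure(data.frame(theta = theta, re = re, im = im),
            class = c("stability_curve", "data.frame"),
            y = y, area = area)
}

#' @export
print.stability_curve <- function(x, ...) {
  cat("ETDRK4 stability boundary, y =", attr(x, "y"),
      "(", nrow(x) - 1, "theta samples, enclosed area",
      signif(attr(x, "area"), 6), ")\n")
  invisible(x)
}
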
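#' Define an extended KiSS reaction-diffusion model
#'
#' The extended Kierstead-Slobodkin (KiSS) model is the scalar
#' reaction-diffusion equation u_t = D Laplacian(u) + tau u^alpha describing a
#' population of density u diffusing at rate D and growing at rate tau; the
#' exponent alpha = 1 recovers the classical linear KiSS critical-patch model
#' and alpha > 1 admits finite-time blow-up.
#'
#' @param D diffusion coefficient (length^2 / time), > 0.
#' @param tau growth rate (1 / time), >= 0 (tau = 0 is pure diffusion).
#' @param alpha growth exponent (dimensionless), > 0.
#' @return an object of class `kiss_model`.
#' @examples
#' kiss_model(D = 1, tau = 1, alpha = 1)
#' @export
kiss_model <- function(D, tau, alpha = 1) {
  stopifnot(is.numeric(D), length(D) == 1, is.numeric(tau), length(tau) == 1,
            is.numeric(alpha), length(alpha) == 1)
  if (!is.finite(D) || D <= 0) stop("D must be a positive diffusion coefficient")
  if (!is.finite(tau) || tau < 0) stop("tau must be a non-negative growth rate")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must satisfy alpha > 0")
  structure(list(D = D, tau = tau, alpha = alpha), class = "kiss_model")
}

#' @export
print.kiss_model <- function(x, ...) {
  cat(sprintf("KiSS model: u_t = D lap(u) + tau u^alpha  (D = %g, tau = %g, alpha = %g)\n",
              x$D, x$tau, x$alpha))
  invisible(x)
}

#' Critical patch size of the linear KiSS model
#'
#' For the linear model (alpha = 1) on \[0, l\] with absorbing ends, the
#' population decays to extinction when l < pi*sqrt(D/tau) and blooms when
#' l > pi*sqrt(D/tau); this function returns that threshold length.
#'
#' @param model a [kiss_model()] with tau > 0.
#' @return the critical length pi*sqrt(D/tau).
#' @examples
#' critical_length(kiss_model(1, 1))   # pi
#' @export
critical_length <- function(model) {
  stopifnot(inherits(model, "kiss_model"))
  if (model$tau == 0)
    stop("no finite critical patch size for tau = 0 (pure diffusion)")
  pi * sqrt(model$D / model$tau)
}

#' Fourier sine coefficients of an initial profile
#'
#' Computes a_n = (2/l) * integral_0^l u0(x) sin(n pi x / l) dx for
#' n = 1..M by composite Simpson quadrature; these are the series weights of
#' the separated solution of the linear model on \[0, l\] with absorbing ends.
#' The quadrature grid is refinable through `n_quad`; for smooth profiles the
#' default resolves the first few dozen modes to roughly 1e-10.
#'
#' @param u0 vectorized function of position on \[0, l\].
#' @param l domain length, > 0.
#' @param M number of modes, >= 1.
#' @param n_quad odd number of Simpson nodes (default 2049).
#' @return numeric vector a_1..a_M.
#' @examples
#' fourier_sine_coefficients(function(x) sin(pi * x), 1, 3)  # ~ (1, 0, 0)
#' @export
fourier_sine_coefficients <- function(u0, l, M, n_quad = 2049L) {
  stopifnot(is.function(u0), l > 0, M >= 1)
  n_quad <- as.integer(n_quad)
  if (n_quad %% 2L == 0L) n_quad <- n_quad + 1L
  x <- seq(0, l, length.out = n_quad)
  fx <- u0(x)
  if (any(!is.finite(fx))) {
    bad <- which(!is.finite(fx))[1]
    stop(sprintf("u0 is non-finite at quadrature node x = %.8g", x[bad]))
  }
  w <- c(1, rep(c(4, 2), length.out = n_quad - 2), 1)
  hq <- l / (n_quad - 1)
  vapply(seq_len(M), function(n) {
    (2 / l) * sum(w * fx * sin(n * pi * x / l)) * hq / 3
  }, numeric(1))
}

#' Analytic series solution of the linear KiSS model
#'
#' Bundles sine-series weights with the model and domain half-parameter so the
#' separated solution u(x,t) = sum_n a_n sin(n pi x / l)
#' exp\[(tau - D n^2 pi^2 / l^2) t\] can be evaluated. The growth exponent
#' carries the diffusion coefficient: mode n decays when l < n*pi*sqrt(D/tau)
#' and grows when l exceeds it, which is what makes l = pi*sqrt(D/tau) the
#' critical patch size.
#'
#' @param model a [kiss_model()]; only alpha = 1 has this solution.
#' @param l domain length (the solution lives on \[0, l\] with u = 0 ends).
#' @param coefficients numeric vector of sine-series weights a_1..a_M.
#' @return an object of class `linear_kiss_solution`.
#' @export
linear_kiss_solution <- function(model, l, coefficients) {
  stopifnot(inherits(model, "kiss_model"), l > 0, length(coefficients) >= 1,
            all(is.finite(coefficients)))
  if (model$alpha != 1)
    stop("the separated series solution exists only for alpha = 1")
  structure(list(model = model, l = l, a = as.numeric(coefficients),
                 M = length(coefficients)),
            class = "linear_kiss_solution")
}

#' Evaluate the linear KiSS series solution
#'
#' @param x positions in \[0, l\] (vector allowed).
#' @param t time >= 0 (scalar).
#' @param sol a [linear_kiss_solution()].
#' @return densities u(x, t).
#' @examples
#' m <- kiss_model(1, 1)
#' s <- linear_kiss_solution(m, l = critical_length(m), coefficients = 1)
#' linear_kiss_series(pi / 2, t = 3, s)  # stationary: sin(pi*(pi/2)/pi) = 1
#' @export
linear_kiss_series <- function(x, t, sol) {
  stopifnot(inherits(sol, "linear_kiss_solution"))
  if (t < 0) stop("t must be >= 0")
  l <- sol$l; m <- sol$model
  n <- seq_len(sol$M)
  growth <- exp((m$tau - m$D * n^2 * pi^2 / l^2) * t)
  drop(sin(outer(x, n) * (pi / l)) %*% (sol$a * growth))
}

.erf <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1

#' Heat-kernel solution of the diffusion-only limit
#'
#' For tau = 0 and a point release u(x,0) = delta(x), the density is the
#' Gaussian kernel u(x,t) = exp(-x^2/(4Dt)) / sqrt(4 pi D t): even in x, of
#' unit mass, with peak height 1/sqrt(4 pi D t).
#'
#' @param x positions (vector allowed).
#' @param t time > 0.
#' @param D diffusion coefficient > 0.
#' @return densities u(x, t).
#' @export
heat_kernel_solution <- function(x, t, D) {
  if (t <= 0) stop("the heat kernel requires t > 0")
  stopifnot(D > 0)
  exp(-x^2 / (4 * D * t)) / sqrt(4 * pi * D * t)
}

#' Diffusing step-front solution
#'
#' For tau = 0 and a step initial profile occupying x < 0, the density is
#' u(x,t) = (1/sqrt(pi)) * integral from x/sqrt(4Dt) to l of exp(-xi^2) d xi,
#' evaluated through the error function. With l = Inf this is the
#' complementary-error-function front decaying from 1 (far left) to 0
#' (far right).
#'
#' @param x positions (vector allowed).
#' @param t time > 0.
#' @param D diffusion coefficient > 0.
#' @param l upper integration limit (default Inf).
#' @return densities u(x, t).
#' @export
step_front_solution <- function(x, t, D, l = Inf) {
  if (t <= 0) stop("the step-front solution requires t > 0")
  stopifnot(D > 0)
  (.erf(l) - .erf(x / sqrt(4 * D * t))) / 2
}
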
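# ETD coefficient sets: exponential weights materialized for a fixed (L, h).
#
# For a diagonal operator the weights are per-mode arrays applied through the
# operator's transform; for a dense 1-D operator they are materialized as real
# matrices V diag(w(lambda h)) V^-1; for a tensor 2-D operator they act in the
# per-axis eigenbases on the mode matrix w(lambda_x + lambda_y), so the
# Kronecker-sum matrix is never formed.

.etd_basis <- function(L) {
  eig1 <- function(A) {
    sym <- isSymmetric(A, tol = 1e-10)
    e <- eigen(A, symmetric = sym)
    if (is.complex(e$values)) {
      if (max(abs(Im(e$values))) > 1e-8 * max(abs(e$values)))
        stop("per-axis operator has genuinely complex spectrum; ",
             "use the spectral discretization path")
      e$values <- Re(e$values); e$vectors <- Re(e$vectors)
    }
    Vinv <- if (sym) t(e$vectors) else tryCatch(solve(e$vectors),
      error = function(e2) stop("per-axis operator is defective to tolerance; ",
                                "use the spectral discretization path"))
    list(values = e$values, V = e$vectors, Vinv = Vinv)
  }
  switch(L$rep,
    diagonal = list(kind = "diagonal", op = L),
    dense = c(list(kind = "dense"), eig1(L$mat)),
    tensor = list(kind = "tensor", x = eig1(L$Ax), y = eig1(L$Ay)),
    stop("unknown operator representation"))
}

.etd_spectrum <- function(basis, h) {
  switch(basis$kind,
    diagonal = h * basis$op$symbol,
    dense = h * basis$values,
    tensor = h * outer(basis$x$values, basis$y$values, `+`))
}

# materialize one weight (per-mode values `vals` over the spectrum) for a basis
.etd_materialize <- function(basis, vals) {
  switch(basis$kind,
    diagonal = vals,
    dense = Re(basis$V %*% (vals * basis$Vinv)),
    tensor = vals)
}

.etd_apply <- function(coeffs, name, v) {
  w <- coeffs$weights[[name]]
  b <- coeffs$basis
  switch(b$kind,
    diagonal = .apply_diagonal(b$op, w, v),
    dense = drop(w %*% v),
    tensor = b$x$V %*% ((b$x$Vinv %*% v %*% t(b$y$Vinv)) * w) %*% t(b$y$V))
}

#' Precompute ETDRK4 exponential coefficients for a fixed (L, h)
#'
#' @param L a `linear_operator` (or numeric vector, taken as plain diagonal).
#' @param h time step > 0.
#' @param contour_points,cutoff passed to [phi_weights()].
#' @return an object of class `etd_coefficients` holding E = e^{Lh},
#'   E2 = e^{Lh/2}, Q and the three bracket weights Wu, Wab, Wc, in the form
#'   suited to the operator representation.
#' @export
etdrk4_coefficients <- function(L, h, contour_points = 32L, cutoff = 0.5) {
  stopifnot(h > 0)
  if (is.numeric(L) && is.null(attr(L, "class")))
    L <- .linear_operator("diagonal", symbol = L, transform = "none")
  basis <- .etd_basis(L)
  z <- .etd_spectrum(basis, h)
  w <- phi_weights(z, h, contour_points, cutoff)
  weights <- lapply(w, function(vals) .etd_materialize(basis, vals))
  structure(list(basis = basis, weights = weights, h = h, scheme = "ETDRK4"),
            class = "etd_coefficients")
}

#' @export
print.etd_coefficients <- function(x, ...) {
  cat("ETD coefficients (", x$scheme, ", ", x$basis$kind,
      " basis, h = ", x$h, ")\n", sep = "")
  invisible(x)
}

#' One ETDRK4 step
#'
#' Advances u' = Lu + F(u,t) by one step of the fourth-order exponential time
#' differencing Runge-Kutta scheme of Cox-Matthews:
#' a = E2 u + Q F(u,t); b = E2 u + Q F(a, t+h/2);
#' c = E2 a + Q (2 F(b, t+h/2) - F(u,t));
#' u+ = E u + Wu F(u,t) + 2 Wab (F(a)+F(b)) + Wc F(c).
#' The c stage is built from a (not from u), which is the form whose scalar
#' amplification factor matches the exact bivariate expansion in
#' [series_coefficients()].
#'
#' @param system a `semilinear_system`.
#' @param u current state.
#' @param t current time.
#' @param h step (must match the step the coefficients were built for).
#' @param coeffs [etdrk4_coefficients()] for (system$L, h).
#' @return the state at t + h.
#' @export
etdrk4_step <- function(system, u, t, h, coeffs) {
  stopifnot(inherits(coeffs, "etd_coefficients"), coeffs$scheme == "ETDRK4")
  if (abs(h - coeffs$h) > 1e-14 * h)
    stop("coefficients were built for h = ", coeffs$h)
  Ffun <- system$F
  Fu <- Ffun(u, t)
  E2u <- .etd_apply(coeffs, "E2", u)
  a <- E2u + .etd_apply(coeffs, "Q", Fu)
  Fa <- Ffun(a, t + h / 2)
  b <- E2u + .etd_apply(coeffs, "Q", Fa)
  Fb <- Ffun(b, t + h / 2)
  cs <- .etd_apply(coeffs, "E2", a) + .etd_apply(coeffs, "Q", 2 * Fb - Fu)
  Fc <- Ffun(cs, t + h)
  .etd_apply(coeffs, "E", u) + .etd_apply(coeffs, "Wu", Fu) +
    2 * .etd_apply(coeffs, "Wab", Fa + Fb) + .etd_apply(coeffs, "Wc", Fc)
}

# ---- exponential multistep comparators --------------------------------------

.scheme_table <- list(
  ETDRK4    = list(order = 4L, startup = 0L, multistep = FALSE),
  ETDM4     = list(order = 4L, startup = 3L, multistep = TRUE),
  ETDM5     = list(order = 5L, startup = 4L, multistep = TRUE),
  ETDM6     = list(order = 6L, startup = 5L, multistep = TRUE),
  ETDADAMS4 = list(order = 4L, startup = 3L, multistep = TRUE)
)

#' Scheme descriptor
#'
#' @param name one of ETDRK4, ETDM4, ETDM5, ETDM6, ETDADAMS4.
#' @return list with `name`, `order`, `startup_steps`, `multistep`.
#' @export
scheme_spec <- function(name) {
  name <- match.arg(name, names(.scheme_table))
  s <- .scheme_table[[name]]
  list(name = name, order = s$order, startup_steps = s$startup,
       multistep = s$multistep)
}

# coefficients c_{j,0..j} of theta(theta+1)...(theta+j-1)/j! (ascending powers)
.rising_factorial_coef <- function(j) {
  p <- 1
  if (j > 0) for (i in 0:(j - 1)) p <- c(0, p) + c(i * p, 0)
  p / factorial(max(j, 1))
}

#' Precompute exponential multistep coefficients
#'
#' The exponential Adams-Bashforth update of order p is
#' u_{n+1} = e^{hL} u_n + h * sum_{j=0}^{p-1} gamma_j(hL) nabla^j F_n,
#' where nabla^j are backward differences of the stored nonlinear evaluations
#' and gamma_j(z) = sum_m c_{jm} m! phi_{m+1}(z) with c_{jm} the coefficients
#' of the rising factorial theta(theta+1)...(theta+j-1)/j!. ETDM4/5/6 use this
#' Newton (backward-difference) form at orders 4, 5, 6. ETDADAMS4 is the same
#' order-4 interpolant assembled in the monomial basis: the cubic through the
#' last four F values is expressed as sum_m d_m theta^m via a Vandermonde
#' solve and integrated against the exponential kernel, giving weights
#' h m! phi_{m+1}(hL) on the d_m. The two forms agree in exact arithmetic but
#' are distinct implementations.
#'
#' @param L a `linear_operator` or numeric diagonal.
#' @param h time step.
#' @param scheme one of ETDM4, ETDM5, ETDM6, ETDADAMS4.
#' @param contour_points,cutoff passed to [phi_funs()].
#' @return an `etd_coefficients` object for [etd_multistep_step()].
#' @export
etd_multistep_coefficients <- function(L, h, scheme,
                                       contour_points = 32L, cutoff = 1.0) {
  spec <- scheme_spec(scheme)
  if (!spec$multistep) stop("use etdrk4_coefficients() for ETDRK4")
  if (is.numeric(L) && is.null(attr(L, "class")))
    L <- .linear_operator("diagonal", symbol = L, transform = "none")
  basis <- .etd_basis(L)
  z <- .etd_spectrum(basis, h)
  p <- spec$order
  dims <- dim(z)
  phis <- phi_funs(as.vector(z), p, contour_points, cutoff)
  weights <- list(E = .etd_materialize(basis, {
    ev <- exp(z); ev
  }))
  if (spec$name == "ETDADAMS4") {
    for (m in 0:(p - 1)) {
      vals <- h * factorial(m) * phis[, m + 1]
      if (!is.null(dims)) dim(vals) <- dims
      weights[[paste0("P", m)]] <- .etd_materialize(basis, vals)
    }
    vander <- outer(-(0:(p - 1)), 0:(p - 1), `^`)  # nodes theta = 0,-1,-2,-3
    extra <- list(Minv = solve(vander), p = p)
  } else {
    for (j in 0:(p - 1)) {
      cj <- .rising_factorial_coef(j)
      vals <- h * as.vector(phis %*% c(cj * factorial(0:j),
                                       rep(0, p - j - 1)))
      if (!is.null(dims)) dim(vals) <- dims
      weights[[paste0("G", j)]] <- .etd_materialize(basis, vals)
    }
    extra <- list(p = p)
  }
  structure(c(list(basis = basis, weights = weights, h = h,
                   scheme = spec$name), extra),
            class = "etd_coefficients")
}

#' One exponential multistep step
#'
#' @param system a `semilinear_system`.
#' @param Fhist list of the stored nonlinear evaluations, most recent first:
#'   F(u_n), F(u_{n-1}), ...; at least `order` entries are required.
#' @param u current state u_n.
#' @param t current time.
#' @param h step.
#' @param coeffs [etd_multistep_coefficients()] for (system$L, h, scheme).
#' @return the state at t + h.
#' @export
etd_multistep_step <- function(system, Fhist, u, t, h, coeffs) {
  stopifnot(inherits(coeffs, "etd_coefficients"))
  p <- coeffs$p
  if (length(Fhist) < p)
    stop("scheme ", coeffs$scheme, " needs ", p, " stored nonlinear ",
         "evaluations; run ", p - 1, " startup steps (ETDRK4) first")
  out <- .etd_apply(coeffs, "E", u)
  if (coeffs$scheme == "ETDADAMS4") {
    for (m in 0:(p - 1)) {
      d <- 0
      for (j in 0:(p - 1)) d <- d + coeffs$Minv[m + 1, j + 1] * Fhist[[j + 1]]
      out <- out + .etd_apply(coeffs, paste0("P", m), d)
    }
  } else {
    for (j in 0:(p - 1)) {
      nab <- 0
      for (i in 0:j) nab <- nab + (-1)^i * choose(j, i) * Fhist[[i + 1]]
      out <- out + .etd_apply(coeffs, paste0("G", j), nab)
    }
  }
  out
}
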
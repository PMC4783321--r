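#' Assemble the semidiscrete system u' = Lu + F(u, t)
#'
#' Discretizes the KiSS model on a grid: L is D times the discrete Laplacian
#' and F(u) = tau * u^alpha acts nodewise in physical space. Default pairing is
#' `fd4` with dirichlet0 boundaries and `spectral` with periodic boundaries;
#' `dst` offers a sine-transform (odd periodic extension) spectral path for
#' dirichlet0 problems. For non-integer alpha the power is computed as
#' sign(u)*|u|^alpha so that negative densities do not produce complex values.
#'
#' @param model a [kiss_model()].
#' @param grid a [build_grid()] result.
#' @param disc `"fd4"`, `"spectral"` or `"dst"`.
#' @param linearize_growth if TRUE and alpha = 1, fold the growth term tau*u
#'   into L (the system is then purely linear, F = 0, and exponential
#'   integrators propagate it exactly up to the accuracy of exp(Lh)).
#' @return an object of class `semilinear_system`.
#' @examples
#' m <- kiss_model(1, 1, 1)
#' g <- build_grid(grid_spec(1, 0, pi, 101))
#' sys <- assemble_system(m, g)
#' @export
assemble_system <- function(model, grid, disc = c("fd4", "spectral", "dst"),
                            linearize_growth = FALSE) {
  stopifnot(inherits(model, "kiss_model"), inherits(grid, "kiss_grid"))
  disc <- match.arg(disc)
  if (disc == "spectral" && grid$bc != "periodic")
    stop("disc = \"spectral\" requires periodic boundaries; use disc = \"dst\" ",
         "for the sine-transform treatment of dirichlet0 problems")
  if (disc == "dst" && grid$bc != "dirichlet0")
    stop("disc = \"dst\" is the sine-transform path for dirichlet0 grids")
  if (linearize_growth && model$alpha != 1)
    stop("linearize_growth requires alpha = 1")
  L <- switch(disc,
    fd4 = if (grid$dim == 1L) fd4_laplacian_1d(grid, model$D)
          else fd4_laplacian_2d(grid, model$D),
    spectral = spectral_symbol(grid, model$D),
    dst = .dst_symbol_operator(grid, model$D))
  if (linearize_growth) {
    L <- .op_add_scalar(L, model$tau)
    Ffun <- function(u, t) 0 * u
  } else {
    tau <- model$tau; alpha <- model$alpha
    int_alpha <- abs(alpha - round(alpha)) < 1e-12
    Ffun <- if (int_alpha) {
      function(u, t) tau * u^round(alpha)
    } else {
      function(u, t) tau * sign(u) * abs(u)^alpha
    }
  }
  layout <- if (grid$bc == "dirichlet0") "interior" else "all"
  structure(list(L = L, F = Ffun, model = model, grid = grid, disc = disc,
                 layout = layout, linearized = linearize_growth),
            class = "semilinear_system")
}

# add c*I to a linear operator
.op_add_scalar <- function(op, c) {
  switch(op$rep,
    dense = { op$mat <- op$mat + c * diag(nrow(op$mat)); op },
    tensor = { op$Ax <- op$Ax + c * diag(nrow(op$Ax)); op },
    diagonal = { op$symbol <- op$symbol + c; op },
    stop("unknown operator representation"))
}

#' Construct a semilinear system directly from an operator and nonlinearity
#'
#' Low-level constructor used for scalar test problems and oracle checks where
#' the right side is not the KiSS reaction term (e.g. u' = u^2 with L = 0, or
#' u' = g u + lambda u with F(u) = lambda u).
#'
#' @param L a `linear_operator`, or a numeric vector taken as a plain diagonal.
#' @param F function(u, t) evaluated nodewise.
#' @return a `semilinear_system` (no grid attached).
#' @export
semilinear_system <- function(L, F) {
  if (is.numeric(L) && is.null(attr(L, "class")))
    L <- .linear_operator("diagonal", symbol = L, transform = "none")
  stopifnot(inherits(L, "linear_operator"), is.function(F))
  structure(list(L = L, F = F, model = NULL, grid = NULL, disc = "custom",
                 layout = "all", linearized = FALSE),
            class = "semilinear_system")
}

#' @export
print.semilinear_system <- function(x, ...) {
  cat("semilinear system u' = Lu + F(u,t); disc =", x$disc,
      "; operator:", x$L$rep, "\n")
  if (!is.null(x$model)) print(x$model)
  invisible(x)
}

# state vector/matrix from full-node field values, honouring the layout
state_from_field <- function(system, field) {
  g <- system$grid
  if (is.null(g) || system$layout == "all") return(field)
  if (g$dim == 1L) field[2:(g$N[1] - 1L)]
  else field[2:(g$N[1] - 1L), 2:(g$N[2] - 1L), drop = FALSE]
}

# full-node field from the state (boundary nodes restored as zero)
field_from_state <- function(system, state) {
  g <- system$grid
  if (is.null(g) || system$layout == "all") return(state)
  if (g$dim == 1L) {
    out <- numeric(g$N[1])
    out[2:(g$N[1] - 1L)] <- state
    out
  } else {
    out <- matrix(0, g$N[1], g$N[2])
    out[2:(g$N[1] - 1L), 2:(g$N[2] - 1L)] <- state
    out
  }
}

#' Initial state for a system
#'
#' @param system a `semilinear_system` with a grid.
#' @param ic an `initial_condition`, a function of the coordinates, or numeric
#'   full-node values.
#' @return the state (interior unknowns for dirichlet0, all nodes otherwise).
#' @export
initial_state <- function(system, ic) {
  g <- system$grid
  if (is.null(g)) stop("system has no grid; supply the state directly")
  field <- if (inherits(ic, "initial_condition")) {
    evaluate_ic(ic, g)
  } else if (is.function(ic)) {
    if (g$dim == 1L) ic(g$x) else outer(g$x, g$y, ic)
  } else if (is.numeric(ic)) {
    ic
  } else stop("unsupported initial condition")
  state_from_field(system, field)
}

# total mass of a state: h * sum(u); with absorbing ends this equals the
# trapezoidal rule on the full grid because the boundary values vanish
state_mass <- function(system, state) {
  g <- system$grid
  if (is.null(g)) return(sum(state))
  prod(g$h) * sum(state)
}
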
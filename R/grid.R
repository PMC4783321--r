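#' Specify a computational grid
#'
#' @param dim 1 or 2.
#' @param lo,hi domain bounds per axis; scalars are recycled across axes.
#' @param N nodes per axis. For `bc = "dirichlet0"` the endpoints are included
#'   and N >= 7 (the five-point stencil needs two interior neighbours on each
#'   side); for `bc = "periodic"` the right endpoint is identified with the
#'   left, N >= 4 and N must be even (FFT-friendly symbol layout).
#' @param bc boundary kind, `"dirichlet0"` (absorbing, u = 0) or `"periodic"`.
#' @return an object of class `grid_spec`.
#' @examples
#' grid_spec(1, -1, 1, 201)
#' @export
grid_spec <- function(dim, lo, hi, N, bc = c("dirichlet0", "periodic")) {
  bc <- match.arg(bc)
  dim <- as.integer(dim)
  stopifnot(dim %in% c(1L, 2L))
  lo <- rep_len(as.numeric(lo), dim)
  hi <- rep_len(as.numeric(hi), dim)
  N <- rep_len(as.integer(N), dim)
  if (any(hi <= lo)) stop("domain bounds must satisfy hi > lo")
  if (bc == "dirichlet0" && any(N < 7L))
    stop("dirichlet0 grids need N >= 7: the five-point fourth-order stencil ",
         "requires two interior neighbours on each side of every unknown")
  if (bc == "periodic") {
    if (any(N < 4L)) stop("periodic grids need N >= 4")
    if (any(N %% 2L != 0L)) stop("periodic grids need even N for the FFT symbol")
  }
  structure(list(dim = dim, lo = lo, hi = hi, N = N, bc = bc),
            class = "grid_spec")
}

#' Build node coordinates from a grid specification
#'
#' Grid convention: dirichlet0 grids include both endpoints, so
#' h = (hi - lo)/(N - 1) and x_i = lo + i*h for i = 0..N-1; periodic grids
#' identify x_N with x_0, so h = (hi - lo)/N and the right endpoint is not
#' stored.
#'
#' @param spec a [grid_spec()].
#' @return an object of class `kiss_grid`: the spec fields plus `x` (and `y`
#'   in 2-D) node coordinate vectors and spacings `h` (per axis).
#' @examples
#' g <- build_grid(grid_spec(1, -1, 1, 201))
#' g$h   # 0.01
#' @export
build_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  axis_nodes <- function(lo, hi, N) {
    if (spec$bc == "dirichlet0") {
      h <- (hi - lo) / (N - 1)
      list(x = lo + h * (0:(N - 1)), h = h)
    } else {
      h <- (hi - lo) / N
      list(x = lo + h * (0:(N - 1)), h = h)
    }
  }
  ax <- axis_nodes(spec$lo[1], spec$hi[1], spec$N[1])
  g <- c(unclass(spec), list(x = ax$x, h = ax$h))
  if (spec$dim == 2L) {
    ay <- axis_nodes(spec$lo[2], spec$hi[2], spec$N[2])
    g$y <- ay$x
    g$h <- c(ax$h, ay$h)
  }
  structure(g, class = "kiss_grid")
}

#' @export
print.kiss_grid <- function(x, ...) {
  cat(sprintf("%d-D grid, %s, N = %s on [%s, %s], h = %s\n", x$dim, x$bc,
              paste(x$N, collapse = "x"), paste(x$lo, collapse = ", "),
              paste(x$hi, collapse = ", "),
              paste(signif(x$h, 6), collapse = ", ")))
  invisible(x)
}

# values of an initial condition on all grid nodes (vector in 1-D, matrix in 2-D)
evaluate_ic <- function(ic, grid) {
  stopifnot(inherits(ic, "initial_condition"), inherits(grid, "kiss_grid"))
  if (!is.na(ic$dim) && ic$dim != grid$dim)
    stop("initial condition '", ic$name, "' is ", ic$dim, "-D but the grid is ",
         grid$dim, "-D")
  if (grid$dim == 1L) {
    ic$fun(grid$x)
  } else {
    outer(grid$x, grid$y, ic$fun)
  }
}
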
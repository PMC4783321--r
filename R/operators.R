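# Linear (diffusion) operators produced by spatial discretization.
#
# Representations:
#   dense    -- a dense matrix acting on the state vector (1-D FD4)
#   tensor   -- a pair of 1-D dense operators (Ax, Ay) with the 2-D action
#               L U = Ax U + U t(Ay); the Kronecker sum is never materialized
#   diagonal -- a diagonal symbol, optionally behind a transform ("fft" for
#               periodic Fourier modes, "dst" for the odd-extension sine
#               transform of Dirichlet problems, "none" for plain diagonal)

.linear_operator <- function(rep, ...) {
  structure(c(list(rep = rep), list(...)), class = "linear_operator")
}

#' @export
print.linear_operator <- function(x, ...) {
  cat("linear operator (", x$rep,
      if (!is.null(x$transform)) paste0(", transform = ", x$transform), ")\n",
      sep = "")
  invisible(x)
}

# 1-D FD4 second-derivative matrix on the state nodes, scaled by `scale`.
# dirichlet0: unknowns are the N-2 interior nodes; the wall value is 0 and the
# ghost node just outside each wall is the odd reflection of the first interior
# node (u_{-1} = -u_1), which preserves fourth-order accuracy for profiles
# vanishing at the wall. periodic: all N nodes, cyclic stencil.
.fd4_matrix <- function(N, h, bc, scale = 1) {
  w <- c(-1, 16, -30, 16, -1) / (12 * h^2)
  if (bc == "dirichlet0") {
    n <- N - 2L
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (s in -2:2) {
        j <- i + s
        if (j >= 1 && j <= n) A[i, j] <- A[i, j] + w[s + 3]
        else if (j == -1) A[i, 1] <- A[i, 1] - w[s + 3]       # ghost: -u_1
        else if (j == n + 2) A[i, n] <- A[i, n] - w[s + 3]    # ghost: -u_n
        # j == 0 or j == n+1: wall node, value 0
      }
    }
    scale * A
  } else {
    A <- matrix(0, N, N)
    for (i in seq_len(N)) {
      for (s in -2:2) {
        j <- ((i - 1 + s) %% N) + 1
        A[i, j] <- A[i, j] + w[s + 3]
      }
    }
    scale * A
  }
}

#' Fourth-order finite-difference Laplacian in one dimension
#'
#' Builds the dense operator for the five-point fourth-order central stencil
#' (-1, 16, -30, 16, -1)/(12 h^2), scaled by the diffusion coefficient.
#' For absorbing (dirichlet0) boundaries the operator acts on the N-2 interior
#' unknowns with the wall held at zero and ghost nodes closed by odd
#' reflection; for periodic boundaries it acts cyclically on all N nodes.
#'
#' @param grid a 1-D [build_grid()] result.
#' @param D scale factor (diffusion coefficient), default 1.
#' @return a `linear_operator` with representation `"dense"`.
#' @export
fd4_laplacian_1d <- function(grid, D = 1) {
  stopifnot(inherits(grid, "kiss_grid"), grid$dim == 1L)
  .linear_operator("dense", mat = .fd4_matrix(grid$N[1], grid$h[1], grid$bc, D),
                   h = grid$h[1], scale = D, bc = grid$bc)
}

#' Fourth-order finite-difference Laplacian in two dimensions
#'
#' Keeps the operator in tensor form L U = Ax U + U t(Ay) where Ax, Ay are the
#' 1-D fourth-order operators along each axis; the full Kronecker-sum matrix is
#' never formed.
#'
#' @param grid a 2-D [build_grid()] result (both axes share the boundary kind).
#' @param D scale factor (diffusion coefficient), default 1.
#' @return a `linear_operator` with representation `"tensor"`.
#' @export
fd4_laplacian_2d <- function(grid, D = 1) {
  stopifnot(inherits(grid, "kiss_grid"), grid$dim == 2L)
  Ax <- .fd4_matrix(grid$N[1], grid$h[1], grid$bc, D)
  Ay <- .fd4_matrix(grid$N[2], grid$h[2], grid$bc, D)
  .linear_operator("tensor", Ax = Ax, Ay = Ay, h = grid$h, scale = D,
                   bc = grid$bc)
}

# Fourier wavenumbers for N periodic nodes on a domain of length len
.fft_wavenumbers <- function(N, len) {
  (2 * pi / len) * c(0:(N / 2 - 1), -(N / 2):-1)
}

#' Spectral Laplacian symbol
#'
#' For periodic boundaries the Laplacian diagonalizes in Fourier space with
#' symbol -D k^2 per mode (zero mode has symbol 0); the operator is applied by
#' FFT round trips. For dirichlet0 grids use the sine-transform path offered by
#' [assemble_system()] (`disc = "dst"`), which diagonalizes the Dirichlet
#' Laplacian through an odd periodic extension.
#'
#' @param grid a [build_grid()] result with periodic boundaries.
#' @param D scale factor (diffusion coefficient), default 1.
#' @return a `linear_operator` with representation `"diagonal"` and
#'   transform `"fft"`; field `symbol` holds -D k^2 (vector in 1-D, matrix of
#'   -D (kx^2 + ky^2) in 2-D).
#' @export
spectral_symbol <- function(grid, D = 1) {
  stopifnot(inherits(grid, "kiss_grid"))
  if (grid$bc != "periodic")
    stop("the Fourier spectral symbol requires periodic boundaries; ",
         "for dirichlet0 use the sine-transform option (disc = \"dst\" in ",
         "assemble_system)")
  if (grid$dim == 1L) {
    k <- .fft_wavenumbers(grid$N[1], grid$hi[1] - grid$lo[1])
    sym <- -D * k^2
  } else {
    kx <- .fft_wavenumbers(grid$N[1], grid$hi[1] - grid$lo[1])
    ky <- .fft_wavenumbers(grid$N[2], grid$hi[2] - grid$lo[2])
    sym <- -D * outer(kx^2, ky^2, `+`)
  }
  .linear_operator("diagonal", symbol = sym, transform = "fft", scale = D,
                   bc = grid$bc, dim = grid$dim)
}

# sine-transform (odd-extension) symbol for dirichlet0 grids: mode n has
# wavenumber n*pi/(hi-lo), n = 1..N-2 over the interior unknowns
.dst_symbol_operator <- function(grid, D = 1) {
  stopifnot(grid$bc == "dirichlet0")
  len <- grid$hi - grid$lo
  if (grid$dim == 1L) {
    k <- pi * seq_len(grid$N[1] - 2L) / len[1]
    sym <- -D * k^2
  } else {
    kx <- pi * seq_len(grid$N[1] - 2L) / len[1]
    ky <- pi * seq_len(grid$N[2] - 2L) / len[2]
    sym <- -D * outer(kx^2, ky^2, `+`)
  }
  .linear_operator("diagonal", symbol = sym, transform = "dst", scale = D,
                   bc = grid$bc, dim = grid$dim)
}

# ---- transforms -------------------------------------------------------------

# forward sine transform of an interior vector via odd periodic extension;
# returns sine-mode coefficients b_n with v_j = sum_n b_n sin(n pi j/(N-1))
.dst_fwd <- function(v) {
  n <- length(v)
  ext <- c(0, v, 0, -rev(v))
  ft <- stats::fft(ext)
  -Im(ft[2:(n + 1)]) / (n + 1)
}

.dst_inv <- function(b) {
  n <- length(b)
  ext <- complex(real = rep(0, 2 * (n + 1)))
  ext[2:(n + 1)] <- complex(imaginary = -b * (n + 1))
  ext[(n + 3):(2 * n + 2)] <- Conj(ext[(n + 1):2])
  Re(stats::fft(ext, inverse = TRUE))[2:(n + 1)] / (2 * (n + 1))
}

# apply a per-mode multiplier through the operator's transform
.apply_diagonal <- function(op, mult, v) {
  if (op$transform == "none") {
    mult * v
  } else if (op$transform == "fft") {
    if (is.matrix(v)) {
      Re(stats::fft(mult * stats::fft(v), inverse = TRUE)) / length(v)
    } else {
      Re(stats::fft(mult * stats::fft(v), inverse = TRUE)) / length(v)
    }
  } else if (op$transform == "dst") {
    if (is.matrix(v)) {
      b <- apply(v, 2, .dst_fwd)
      b <- t(apply(b, 1, .dst_fwd))
      w <- mult * b
      w <- apply(w, 2, .dst_inv)
      t(apply(w, 1, .dst_inv))
    } else {
      .dst_inv(mult * .dst_fwd(v))
    }
  } else stop("unknown transform")
}

#' Apply a linear operator to a state
#'
#' @param op a `linear_operator`.
#' @param v state: vector (1-D / diagonal) or matrix (2-D tensor / spectral).
#' @return L v in the same shape.
#' @export
apply_operator <- function(op, v) {
  stopifnot(inherits(op, "linear_operator"))
  switch(op$rep,
    dense = drop(op$mat %*% v),
    tensor = op$Ax %*% v + v %*% t(op$Ay),
    diagonal = .apply_diagonal(op, op$symbol, v),
    stop("unknown operator representation"))
}
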
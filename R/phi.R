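# Numerically stable evaluation of the exponential-integrator weights.
#
# The ETDRK4 update uses, per mode z = lambda*h:
#   E   = e^z,  E2 = e^{z/2},
#   Q   = h (e^{z/2} - 1)/z
#   W_u = h (-4 - z + e^z (4 - 3z + z^2))/z^3
#   W_ab= h ( 2 + z + e^z (-2 + z))/z^3
#   W_c = h (-4 - 3z - z^2 + e^z (4 - z))/z^3
# All four quotients are entire functions with removable singularities at 0
# (limits h/2, h/6, h/6, h/6); evaluating the closed forms directly near 0
# loses all accuracy to cancellation, so for |z| below a cutoff they are
# computed as the mean of the closed form over M points on a unit-radius
# contour centred at z (Kassam-Trefethen).

.contour_mean <- function(z, f, M) {
  pts <- exp(2i * pi * (seq_len(M) - 0.5) / M)
  vapply(z, function(zz) mean(f(zz + pts)), complex(1))
}

# evaluate closed-form f stably over a vector/matrix of modes z; real z keeps
# real arithmetic on the direct branch (the formulas are real there)
.stable_eval <- function(z, f, M = 32L, cutoff = 0.5) {
  dims <- dim(z)
  z <- as.vector(z)
  out <- if (is.numeric(z)) complex(real = rep(0, length(z)))
         else complex(length(z))
  big <- Mod(z) >= cutoff
  if (any(big)) out[big] <- f(z[big])
  if (any(!big)) out[!big] <- .contour_mean(z[!big], f, M)
  if (!is.null(dims)) dim(out) <- dims
  out
}

#' ETDRK4 exponential weights for a (vector of) linear modes
#'
#' Computes e^z, e^{z/2} and the four phi-based bracket weights of the ETDRK4
#' update for z = lambda*h, using the closed forms when |z| >= `cutoff` and the
#' mean over a unit-radius contour of `contour_points` points centred at z
#' otherwise. The weights carry the step factor h: as z -> 0 they tend to
#' Q = h/2 and W_u = W_ab = W_c = h/6, and z = 0 is handled without any
#' division by zero.
#'
#' @param z numeric or complex vector of modes lambda*h.
#' @param h time step (multiplies Q and the W weights).
#' @param contour_points number of contour points (default 32).
#' @param cutoff modulus below which the contour evaluation is used.
#' @return list with fields `E`, `E2`, `Q`, `Wu`, `Wab`, `Wc`, each the shape
#'   of `z`; real if `z` is real.
#' @examples
#' w <- phi_weights(0, h = 1)
#' c(w$Q, w$Wu)  # 0.5, 1/6
#' @export
phi_weights <- function(z, h = 1, contour_points = 32L, cutoff = 0.5) {
  was_real <- is.numeric(z)
  out <- list(
    E  = exp(z),
    E2 = exp(z / 2),
    Q  = h * .stable_eval(z, function(s) (exp(s / 2) - 1) / s,
                          contour_points, cutoff),
    Wu = h * .stable_eval(z, function(s)
      (-4 - s + exp(s) * (4 - 3 * s + s^2)) / s^3, contour_points, cutoff),
    Wab = h * .stable_eval(z, function(s)
      (2 + s + exp(s) * (-2 + s)) / s^3, contour_points, cutoff),
    Wc = h * .stable_eval(z, function(s)
      (-4 - 3 * s - s^2 + exp(s) * (4 - s)) / s^3, contour_points, cutoff))
  if (was_real) out[c("Q", "Wu", "Wab", "Wc")] <-
      lapply(out[c("Q", "Wu", "Wab", "Wc")], Re)
  out
}

#' phi-functions of exponential integrators
#'
#' Evaluates phi_1..phi_kmax at the modes z, where phi_1(z) = (e^z - 1)/z and
#' phi_{k+1}(z) = (phi_k(z) - 1/k!)/z, with phi_k(0) = 1/k!. For |z| below the
#' cutoff the recurrence is evaluated on a unit contour centred at z and
#' averaged, which avoids the cancellation that makes the direct recurrence
#' useless near the origin.
#'
#' @param z numeric or complex vector.
#' @param kmax highest phi index needed.
#' @param contour_points,cutoff as in [phi_weights()].
#' @return matrix (length(z) x kmax) with column k holding phi_k(z).
#' @export
phi_funs <- function(z, kmax, contour_points = 32L, cutoff = 1.0) {
  was_real <- is.numeric(z)
  rec <- function(s) {
    out <- matrix(0i, length(s), kmax)
    p <- (exp(s) - 1) / s
    out[, 1] <- p
    if (kmax > 1) for (k in 2:kmax) {
      p <- (p - 1 / factorial(k - 1)) / s
      out[, k] <- p
    }
    out
  }
  z <- as.vector(z)
  out <- matrix(0i, length(z), kmax)
  big <- Mod(z) >= cutoff
  if (any(big)) out[big, ] <- rec(as.complex(z[big]))
  if (any(!big)) {
    pts <- exp(2i * pi * (seq_len(contour_points) - 0.5) / contour_points)
    for (i in which(!big)) {
      out[i, ] <- colMeans(rec(z[i] + pts))
    }
  }
  if (was_real) out <- Re(out)
  out
}
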
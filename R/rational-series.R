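# Exact rational arithmetic on truncated power series.
#
# Coefficients are rationals stored as numerator/denominator pairs in doubles;
# every operation reduces by gcd and aborts if a numerator or denominator
# leaves the exactly-representable integer range (< 2^53), so results are
# exact or an error -- never silently rounded.

.rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    nz <- b > 0
    t <- b[nz]
    b[nz] <- a[nz] %% b[nz]
    a[nz] <- t
  }
  a
}

.rat_check <- function(x) {
  if (any(abs(x) >= 2^53))
    stop("exact rational arithmetic overflowed the double-integer range")
  x
}

# normalize vectors of rationals n/d: positive denominator, gcd-reduced
.rat_norm <- function(n, d) {
  if (any(d == 0)) stop("zero denominator in rational arithmetic")
  s <- sign(d)
  n <- n * s
  d <- d * s
  g <- .rat_gcd(n, d)
  g[g == 0] <- 1
  list(n = .rat_check(n / g), d = .rat_check(d / g))
}

.rat_add <- function(a, b) .rat_norm(a$n * b$d + b$n * a$d, a$d * b$d)
.rat_mul <- function(a, b) .rat_norm(a$n * b$n, a$d * b$d)

# a truncated series sum_k (n_k/d_k) y^k, k = 0..K
rs_new <- function(n, d = rep(1, length(n))) .rat_norm(n, d)

rs_const <- function(num, den = 1, K) {
  rs_new(c(num, rep(0, K)), c(den, rep(1, K)))
}

rs_len <- function(a) length(a$n)

rs_add <- function(a, b) {
  K <- min(rs_len(a), rs_len(b))
  .rat_add(list(n = a$n[seq_len(K)], d = a$d[seq_len(K)]),
           list(n = b$n[seq_len(K)], d = b$d[seq_len(K)]))
}

rs_scale <- function(a, num, den = 1) {
  .rat_norm(a$n * num, a$d * den)
}

rs_mul <- function(a, b) {
  K <- min(rs_len(a), rs_len(b))
  n <- rep(0, K); d <- rep(1, K)
  for (k in seq_len(K)) {
    acc <- list(n = 0, d = 1)
    for (i in seq_len(k)) {
      term <- .rat_mul(list(n = a$n[i], d = a$d[i]),
                       list(n = b$n[k - i + 1], d = b$d[k - i + 1]))
      acc <- .rat_add(acc, term)
    }
    n[k] <- acc$n; d[k] <- acc$d
  }
  list(n = n, d = d)
}

# divide by y^m, requiring the m lowest coefficients to vanish exactly
rs_shift_down <- function(a, m) {
  if (m == 0) return(a)
  if (any(a$n[seq_len(m)] != 0))
    stop("series not divisible by y^", m, ": low-order terms do not vanish")
  list(n = a$n[-seq_len(m)], d = a$d[-seq_len(m)])
}

# exp(c*y) truncated at order K: coefficients c^k / k!
rs_exp <- function(num, den, K) {
  n <- num^.rat_check(0:K)
  d <- den^(0:K) * factorial(0:K)
  .rat_norm(.rat_check(n), .rat_check(d))
}

rs_values <- function(a) a$n / a$d

# ---- bivariate polynomials in x (degree <= 4) with series-in-y coefficients

bp_const <- function(series_list) series_list

bp_zero <- function(K, deg = 4) {
  lapply(seq_len(deg + 1), function(i) rs_const(0, 1, K))
}

bp_add <- function(p, q) {
  mapply(rs_add, p, q, SIMPLIFY = FALSE)
}

bp_scale <- function(p, num, den = 1) lapply(p, rs_scale, num = num, den = den)

# multiply two x-polynomials; degree must stay within length(p)+length(q)-2 <= 4
bp_mul <- function(p, q, K) {
  dp <- length(p) - 1; dq <- length(q) - 1
  out <- lapply(seq_len(dp + dq + 1), function(i) rs_const(0, 1, K))
  for (i in 0:dp) {
    for (j in 0:dq) {
      out[[i + j + 1]] <- rs_add(out[[i + j + 1]], rs_mul(p[[i + 1]], q[[j + 1]]))
    }
  }
  out
}

# multiply by x (shift coefficients up one degree)
bp_shift_x <- function(p, K) {
  c(list(rs_const(0, 1, K)), p)
}
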
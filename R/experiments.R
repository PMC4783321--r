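#' Relative L2 error between a reference and a computed solution
#'
#' Returns sqrt( sum_j (e_j - c_j)^2 / sum_j e_j^2 ) over the supplied nodes
#' (the solver's accuracy metric; zero iff the two vectors coincide).
#'
#' @param e reference values.
#' @param c computed values.
#' @return non-negative scalar.
#' @examples
#' l2_error(c(3, 4), c(3, 0))   # 4/5
#' @export
l2_error <- function(e, c) {
  if (length(e) != length(c)) stop("reference and computed lengths differ")
  denom <- sum(e^2)
  if (denom == 0) stop("reference has zero norm; relative L2 error undefined")
  sqrt(sum((e - c)^2) / denom)
}

#' The one-dimensional nonlinear benchmark problem
#'
#' The standard 1-D test configuration: D = 0.5, tau = 0.5, alpha = 2 on
#' \[-1, 1\] with absorbing ends, u0 = sin(2 pi x), integrated to T = 1.
#'
#' @param N nodes (default 200).
#' @return a scenario list (`model`, `grid`, `ic`, `T`, `disc`).
#' @export
table1_problem <- function(N = 200L) {
  list(model = kiss_model(D = 0.5, tau = 0.5, alpha = 2),
       grid = grid_spec(1, -1, 1, N, "dirichlet0"),
       ic = catalog_ic("sin2pix"),
       T = 1, disc = "fd4")
}

#' Convergence and timing study
#'
#' For each (scheme, k) pair: integrate the problem to T, measure the relative
#' L2 error of the final state against the reference on the solver's nodes,
#' and log the wall time (informational only -- hardware dependent, never a
#' correctness surface). The reference is either ETDRK4 on the same spatial
#' grid at `k_ref` (`reference = "etdrk4_fine"`, the only option for nonlinear
#' problems, which have no closed form) or the analytic sine series
#' (`reference = "analytic"`, alpha = 1 only; supply `ref_solution`).
#'
#' @param problem scenario list as from [table1_problem()].
#' @param schemes character vector of scheme names.
#' @param ks numeric vector of time steps.
#' @param reference `"etdrk4_fine"` or `"analytic"`.
#' @param k_ref reference step for `"etdrk4_fine"` (default 1/8192).
#' @param ref_solution a [linear_kiss_solution()] for `"analytic"`.
#' @param csv optional path; if given, the table is written as CSV with
#'   columns `method,k,l2,cpu_s`.
#' @return data frame (class `error_report`) with columns `method`, `k`, `l2`,
#'   `cpu_s`, `blowup`; attribute `reference` records the policy.
#' @export
convergence_study <- function(problem, schemes = "ETDRK4", ks,
                              reference = c("etdrk4_fine", "analytic"),
                              k_ref = 1 / 8192, ref_solution = NULL,
                              csv = NULL) {
  reference <- match.arg(reference)
  grid <- build_grid(problem$grid)
  system <- assemble_system(problem$model, grid, problem$disc %||% "fd4")
  Tfin <- problem$T
  if (reference == "etdrk4_fine") {
    ref <- integrate_kiss(system, problem$ic, T = Tfin, k = k_ref)
    if (ref$blowup$flag) stop("reference run blew up before T")
    e <- ref$final_state
    ref_desc <- sprintf("ETDRK4, k_ref = %g, same grid", k_ref)
  } else {
    if (is.null(ref_solution))
      stop("reference = \"analytic\" needs ref_solution (linear_kiss_solution)")
    xs <- grid$x[2:(grid$N[1] - 1)]
    e <- linear_kiss_series(xs - grid$lo[1], Tfin, ref_solution)
    ref_desc <- sprintf("analytic sine series, M = %d", ref_solution$M)
  }
  rows <- list()
  for (scheme in schemes) {
    for (k in ks) {
      tm <- proc.time()[["elapsed"]]
      res <- integrate_kiss(system, problem$ic, T = Tfin, k = k,
                            scheme = scheme)
      cpu <- proc.time()[["elapsed"]] - tm
      l2 <- if (res$blowup$flag) NA_real_ else l2_error(e, res$final_state)
      rows[[length(rows) + 1]] <- data.frame(
        method = scheme, k = k, l2 = l2, cpu_s = cpu,
        blowup = res$blowup$flag)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "reference") <- ref_desc
  class(out) <- c("error_report", "data.frame")
  if (!is.null(csv)) {
    utils::write.csv(
      data.frame(method = out$method, k = out$k,
                 l2 = sprintf("%.6e", out$l2), cpu_s = sprintf("%.4f", out$cpu_s)),
      csv, row.names = FALSE, quote = FALSE)
  }
  out
}

#' @export
print.error_report <- function(x, ...) {
  cat("convergence study (reference:", attr(x, "reference"), ")\n")
  df <- as.data.frame(x)
  df$l2 <- sprintf("%.4e", df$l2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Run a simulation scenario
#'
#' Thin wrapper tying model, grid, initial condition and integrator together;
#' used by the bundled 1-D and 2-D pattern scenarios.
#'
#' @param model a [kiss_model()].
#' @param grid a [grid_spec()] (or built grid).
#' @param ic an `initial_condition` (or function / field values).
#' @param T,k final time and step (T/k integral).
#' @param scheme integrator name.
#' @param snapshot_times snapshot times on the step grid (default: T).
#' @param disc discretization (`"fd4"`, `"spectral"`, `"dst"`).
#' @param ... further arguments to [integrate_kiss()].
#' @return a `simulation_result`.
#' @export
run_scenario <- function(model, grid, ic, T, k, scheme = "ETDRK4",
                         snapshot_times = NULL, disc = "fd4", ...) {
  if (inherits(grid, "grid_spec")) grid <- build_grid(grid)
  system <- assemble_system(model, grid, disc)
  integrate_kiss(system, ic, T = T, k = k, scheme = scheme,
                 snapshot_times = snapshot_times, ...)
}

#' Empirical critical patch size from integration sweeps
#'
#' For the linear model (alpha = 1) on \[0, l\] seeded with the fundamental
#' mode sin(pi x / l), the growth indicator log(max|u(T)| / max|u(0)|) is
#' negative below the critical patch size and positive above it. The sweep
#' evaluates the indicator over `l_values`, brackets the sign change, and
#' refines the bracket by bisection on l down to a relative width `l_tol`,
#' returning the empirical threshold (bracket midpoint).
#'
#' @param model a [kiss_model()] with alpha = 1 and tau > 0.
#' @param l_values domain lengths to sweep (increasing).
#' @param T integration horizon.
#' @param k time step.
#' @param N nodes per grid.
#' @param scheme integrator.
#' @param l_tol relative bracket width at which bisection stops.
#' @return list with `table` (data frame l, indicator), `threshold` (empirical
#'   critical length), `bracket` (final bracketing interval).
#' @export
patch_size_sweep <- function(model, l_values, T = 5, k = 1e-3, N = 200L,
                             scheme = "ETDRK4", l_tol = 2e-3) {
  stopifnot(inherits(model, "kiss_model"), model$tau > 0)
  if (model$alpha != 1)
    stop("the patch-size sweep applies to the linear model (alpha = 1)")
  indicator <- function(l) {
    grid <- build_grid(grid_spec(1, 0, l, N, "dirichlet0"))
    system <- assemble_system(model, grid)
    u0 <- sin(pi * grid$x / l)
    res <- integrate_kiss(system, u0, T = T, k = k, scheme = scheme)
    log(max(abs(res$final_state)) / max(abs(sin(pi * grid$x[2:(N - 1)] / l))))
  }
  l_values <- sort(l_values)
  ind <- vapply(l_values, indicator, numeric(1))
  tab <- data.frame(l = l_values, indicator = ind)
  flip <- which(diff(sign(ind)) > 0)
  if (length(flip) == 0) {
    return(list(table = tab, threshold = NA_real_, bracket = NULL))
  }
  lo <- l_values[flip[1]]; hi <- l_values[flip[1] + 1]
  while ((hi - lo) / (0.5 * (hi + lo)) > l_tol) {
    mid <- 0.5 * (lo + hi)
    if (indicator(mid) < 0) lo <- mid else hi <- mid
  }
  list(table = tab, threshold = 0.5 * (lo + hi), bracket = c(lo, hi))
}
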
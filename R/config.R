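# Run configuration: one versioned YAML layout, validated up front so every
# module precondition fails before any computation starts.

.config_defaults <- list(
  disc = "fd4",
  time = list(scheme = "ETDRK4"),
  output = list(dir = ".", formats = "text"),
  numerics = list(contour_points = 32L, contour_cutoff = 0.5,
                  blowup_threshold = 1e10, reference_k = 1 / 8192)
)

.check_keys <- function(x, allowed, path) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0)
    stop("unknown config key", if (length(extra) > 1) "s", " at ", path, ": ",
         paste(extra, collapse = ", "), " (allowed: ",
         paste(allowed, collapse = ", "), ")")
}

.need <- function(x, key, path) {
  if (is.null(x[[key]])) stop("missing required config key ", path, ".", key)
  x[[key]]
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration (`config_version: 1`), fills documented
#' defaults (disc = fd4, scheme = ETDRK4, contour_points = 32,
#' contour_cutoff = 0.5, blowup_threshold = 1e10, reference_k = 1/8192),
#' and validates every field against the owning module's preconditions before
#' any computation starts; unknown keys are rejected with their key path.
#'
#' @param path YAML file path.
#' @return a validated `run_config` list with elements `model` (kiss_model),
#'   `grid_spec`, `disc`, `ic`, `time`, `output`, `numerics`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  .check_keys(cfg, c("config_version", "model", "domain", "disc", "ic",
                     "time", "output", "numerics"), "<top>")
  ver <- cfg$config_version %||% 1L
  if (ver != 1) stop("unsupported config_version: ", ver)

  mc <- .need(cfg, "model", "<top>")
  .check_keys(mc, c("D", "tau", "alpha"), "model")
  model <- kiss_model(.need(mc, "D", "model"), .need(mc, "tau", "model"),
                      mc$alpha %||% 1)

  dc <- .need(cfg, "domain", "<top>")
  # YAML 1.1 reads a bare `N` key as boolean FALSE; restore the documented name
  names(dc)[names(dc) %in% c("FALSE", "no")] <- "N"
  .check_keys(dc, c("dim", "lo", "hi", "N", "bc"), "domain")
  gspec <- grid_spec(dc$dim %||% 1L, .need(dc, "lo", "domain"),
                     .need(dc, "hi", "domain"), .need(dc, "N", "domain"),
                     dc$bc %||% "dirichlet0")

  disc <- cfg$disc %||% .config_defaults$disc
  if (!disc %in% c("fd4", "spectral", "dst"))
    stop("config key disc must be one of fd4, spectral, dst")

  ic_cfg <- cfg$ic %||% list(name = "sin2pix")
  .check_keys(ic_cfg, c("name", "params", "file"), "ic")
  ic <- if (!is.null(ic_cfg$file)) ic_from_file(ic_cfg$file)
        else catalog_ic(.need(ic_cfg, "name", "ic"), ic_cfg$params %||% list())

  tc <- .need(cfg, "time", "<top>")
  .check_keys(tc, c("scheme", "k", "T", "snapshot_every", "snapshot_times"),
              "time")
  k <- .need(tc, "k", "time"); Tfin <- .need(tc, "T", "time")
  if (k <= 0 || Tfin <= 0) stop("time.k and time.T must be positive")
  if (abs(Tfin / k - round(Tfin / k)) > 1e-8)
    stop("time.T / time.k = ", Tfin / k,
         " is not an integer step count (no partial final step)")
  scheme <- tc$scheme %||% .config_defaults$time$scheme
  scheme_spec(scheme)  # validates the name
  snapshot_times <- if (!is.null(tc$snapshot_times)) {
    as.numeric(tc$snapshot_times)
  } else if (!is.null(tc$snapshot_every)) {
    seq(tc$snapshot_every, Tfin, by = tc$snapshot_every)
  } else Tfin

  oc <- cfg$output %||% list()
  .check_keys(oc, c("dir", "formats"), "output")
  output <- utils::modifyList(.config_defaults$output, oc)

  nc <- cfg$numerics %||% list()
  .check_keys(nc, c("contour_points", "contour_cutoff", "blowup_threshold",
                    "reference_k"), "numerics")
  numerics <- utils::modifyList(.config_defaults$numerics, nc)

  structure(list(model = model, grid_spec = gspec, disc = disc, ic = ic,
                 time = list(scheme = scheme, k = k, T = Tfin,
                             snapshot_times = snapshot_times),
                 output = output, numerics = numerics),
            class = "run_config")
}

#' Execute a validated configuration
#'
#' @param config a `run_config` from [load_config()].
#' @return a `simulation_result`.
#' @export
run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  grid <- build_grid(config$grid_spec)
  system <- assemble_system(config$model, grid, config$disc)
  integrate_kiss(system, config$ic, T = config$time$T, k = config$time$k,
                 scheme = config$time$scheme,
                 snapshot_times = config$time$snapshot_times,
                 blowup_threshold = config$numerics$blowup_threshold,
                 contour_points = config$numerics$contour_points,
                 cutoff = config$numerics$contour_cutoff)
}

.fmt <- function(x) sprintf("%.17g", x)

#' Write simulation output files
#'
#' Writes snapshots as delimited text with explicit coordinate columns
#' (`x[ y] u`, full double precision), per-step diagnostics as
#' `diagnostics.csv` (`step,t,mass,min,max`), and `metadata.json` recording the
#' convention flags (grid rule, boundary kind, discretization, c-stage
#' variant) plus the scheme and step. A `.incomplete` marker is present while
#' writing and removed on success; re-reading with [read_result()] reproduces
#' the arrays bit-exactly.
#'
#' @param result a `simulation_result`.
#' @param config optional `run_config` echoed into the metadata.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_result <- function(result, config = NULL, dir) {
  stopifnot(inherits(result, "simulation_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(dir, ".incomplete")
  file.create(marker)
  files <- character(0)
  g <- result$grid
  for (i in seq_along(result$snapshots)) {
    f <- file.path(dir, sprintf("snapshot_%03d.txt", i))
    con <- file(f, "w")
    writeLines(c("# kiss-snapshot v1",
                 paste0("# t = ", .fmt(result$times[i])),
                 paste0("# columns: ", if (g$dim == 1L) "x u" else "x y u")),
               con)
    if (g$dim == 1L) {
      writeLines(paste(.fmt(g$x), .fmt(result$snapshots[[i]])), con)
    } else {
      snap <- result$snapshots[[i]]
      xs <- rep(g$x, times = length(g$y))
      ys <- rep(g$y, each = length(g$x))
      writeLines(paste(.fmt(xs), .fmt(ys), .fmt(as.vector(snap))), con)
    }
    close(con)
    files <- c(files, f)
  }
  fdiag <- file.path(dir, "diagnostics.csv")
  d <- result$diagnostics
  writeLines(c("step,t,mass,min,max",
               paste(d$step, .fmt(d$t), .fmt(d$mass), .fmt(d$min), .fmt(d$max),
                     sep = ",")), fdiag)
  files <- c(files, fdiag)
  meta <- list(
    format = "kiss-run v1",
    scheme = result$scheme, k = result$k, T = result$T,
    blowup = result$blowup,
    snapshot_times = result$times,
    conventions = list(
      grid_rule = "dirichlet0: endpoints included, h = (hi-lo)/(N-1); periodic: right endpoint identified, h = (hi-lo)/N",
      bc = g$bc,
      dirichlet_closure = "ghost nodes by odd reflection; walls held at 0",
      c_stage = "a-form (c = E2*a + Q*(2F(b) - F(u)))"),
    grid = list(dim = g$dim, lo = g$lo, hi = g$hi, N = g$N, h = g$h))
  if (!is.null(config) && inherits(config, "run_config")) {
    meta$config_echo <- list(
      model = unclass(config$model), disc = config$disc,
      ic = config$ic$name, time = config$time[c("scheme", "k", "T")],
      numerics = config$numerics)
  }
  fmeta <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, fmeta, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, fmeta)
  file.remove(marker)
  invisible(files)
}

#' Read back simulation output
#'
#' @param dir directory written by [write_result()].
#' @return list with `snapshots`, `times`, `diagnostics`, `metadata`.
#' @export
read_result <- function(dir) {
  if (file.exists(file.path(dir, ".incomplete")))
    stop("output directory is marked incomplete: ", dir)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  snaps <- list(); times <- numeric(0)
  fs <- sort(list.files(dir, pattern = "^snapshot_\\d+\\.txt$",
                        full.names = TRUE))
  for (f in fs) {
    hdr <- readLines(f, n = 2)
    times <- c(times, as.numeric(sub("# t = ", "", hdr[2], fixed = TRUE)))
    tab <- utils::read.table(f, comment.char = "#")
    if (ncol(tab) == 2L) {
      snaps[[length(snaps) + 1]] <- tab[[2]]
    } else {
      nx <- length(unique(tab[[1]]))
      snaps[[length(snaps) + 1]] <- matrix(tab[[3]], nrow = nx)
    }
  }
  diagnostics <- utils::read.csv(file.path(dir, "diagnostics.csv"))
  list(snapshots = snaps, times = times, diagnostics = diagnostics,
       metadata = meta)
}

#' Deterministic miniature test inputs
#'
#' @param kind one of `grid1d_small` (N = 21 on \[-1, 1\]), `grid2d_small`
#'   (21 x 21 on \[-1, 1\]^2), `scalar_ode` (u' = u^2, u0 = 1, exact solution
#'   1/(1-t) attached) or `table1_problem` (the 1-D benchmark, rescaled to
#'   `size` nodes).
#' @param size node count for `table1_problem` (default 50).
#' @return the fixture object; no randomness anywhere.
#' @export
make_fixture <- function(kind = c("grid1d_small", "grid2d_small", "scalar_ode",
                                  "table1_problem"), size = 50L) {
  kind <- match.arg(kind)
  switch(kind,
    grid1d_small = build_grid(grid_spec(1, -1, 1, 21)),
    grid2d_small = build_grid(grid_spec(2, -1, 1, 21)),
    scalar_ode = list(
      system = semilinear_system(0, function(u, t) u^2),
      u0 = 1, exact = function(t) 1 / (1 - t)),
    table1_problem = table1_problem(N = as.integer(size)))
}
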
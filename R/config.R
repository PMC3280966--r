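#' Run configuration
#'
#' Bundles everything that defines a simulation: geometry, parameters,
#' boundary condition, optional growth and noise specifications, mesh
#' resolution, solver tolerances and the seed. Fully serializable to YAML
#' ([save_config()] / [load_config()]) and hash-stable ([config_hash()]).
#'
#' @param geometry A [lung_geometry()].
#' @param params A [param_set()].
#' @param bc A [boundary_condition()].
#' @param growth Optional [growth_spec()].
#' @param noise Optional [noise_spec()].
#' @param hmax Mesh resolution.
#' @param dt Time step.
#' @param t_end Run duration.
#' @param tol Steady-state tolerance.
#' @param seed Base RNG seed.
#' @param outdir Output directory for driver scripts.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(geometry = lung_geometry(), params = reference_params(),
                       bc = boundary_condition("open_farfield"),
                       growth = NULL, noise = NULL,
                       hmax = 0.2, dt = 0.02, t_end = 150, tol = 1e-5,
                       seed = 1L, outdir = "runs") {
  stopifnot(inherits(geometry, "lung_geometry"), inherits(params, "lung_params"))
  structure(list(geometry = geometry, params = params, bc = bc,
                 growth = growth, noise = noise, hmax = hmax, dt = dt,
                 t_end = t_end, tol = tol, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

config_keys <- function() list(
  geometry = names(formals(lung_geometry)),
  params = setdiff(names(formals(param_set)), c("kon", "koff")),
  growth = c("mode", "v", "mu", "ratio", "wtip"),
  noise = c("sd", "ell", "replicates", "seed"),
  top = c("geometry", "params", "bc", "growth", "noise", "hmax", "dt",
          "t_end", "tol", "seed", "outdir"))

#' Save a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(geometry = unclass(config$geometry),
            params = unclass(config$params)[config_keys()$params],
            bc = config$bc$kind,
            hmax = config$hmax, dt = config$dt, t_end = config$t_end,
            tol = config$tol, seed = config$seed, outdir = config$outdir)
  if (!is.null(config$growth)) {
    g <- unclass(config$growth)
    x$growth <- g[!vapply(g, is.null, TRUE)]
  }
  if (!is.null(config$noise)) x$noise <- unclass(config$noise)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys (at the top level or inside any section) are rejected with an
#' error listing the offending names; all values are re-validated through the
#' constructors.
#'
#' @param path YAML file written by [save_config()] (or by hand with the same
#'   keys).
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  reject <- function(got, allowed, where) {
    bad <- setdiff(got, allowed)
    if (length(bad))
      stop(sprintf("unknown %s key(s): %s", where, paste(bad, collapse = ", ")),
           call. = FALSE)
  }
  reject(names(x), config_keys()$top, "config")
  reject(names(x$geometry), config_keys()$geometry, "geometry")
  reject(names(x$params), config_keys()$params, "params")
  if (!is.null(x$growth)) reject(names(x$growth), config_keys()$growth, "growth")
  if (!is.null(x$noise)) reject(names(x$noise), config_keys()$noise, "noise")
  growth <- if (is.null(x$growth)) NULL else do.call(growth_spec, x$growth)
  noise <- if (is.null(x$noise)) NULL else do.call(noise_spec, x$noise)
  run_config(geometry = do.call(lung_geometry, x$geometry %||% list()),
             params = do.call(param_set, x$params %||% list()),
             bc = boundary_condition(x$bc %||% "open_farfield"),
             growth = growth, noise = noise,
             hmax = x$hmax %||% 0.2, dt = x$dt %||% 0.02,
             t_end = x$t_end %||% 150, tol = x$tol %||% 1e-5,
             seed = x$seed %||% 1L, outdir = x$outdir %||% "runs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a run configuration
#'
#' Builds the mesh and runs either the fixed-domain steady-state solve or
#' the growing-domain integration, returning the trajectory together with
#' its pattern report and provenance (config hash, seed).
#'
#' @param config A [run_config()].
#' @return List with \code{trajectory}, \code{report} (pattern), optional
#'   \code{solve} report, and \code{hash}.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  final_height <- NULL
  if (!is.null(config$growth)) {
    g <- config$growth
    h0 <- effective_stalk(config$geometry)
    cap <- config$geometry$Rc * config$geometry$tip_mesenchyme_scale +
      config$geometry$Lfar
    final_height <- if (g$mode == "uniform")
      uniform_growth_height(h0, g$mu, config$t_end) + cap
    else h0 + cap + g$v * config$t_end
  }
  mesh <- make_mesh(config$geometry, hmax = config$hmax,
                    final_height = final_height)
  hash <- config_hash(lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x))
  if (is.null(config$growth)) {
    rep <- run_to_steady(mesh, config$params, bc = config$bc,
                         tol = config$tol, t_max = config$t_end,
                         dt = config$dt, seed = config$seed)
    list(trajectory = rep$trajectory, report = pattern_report(rep$trajectory),
         solve = rep, hash = hash)
  } else {
    traj <- grow_and_solve(mesh, config$params, config$growth,
                           t_end = config$t_end, bc = config$bc,
                           dt = config$dt, seed = config$seed)
    list(trajectory = traj, report = pattern_report(traj), hash = hash)
  }
}
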
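#' Boundary condition for the outer domain boundary
#'
#' \code{"open_farfield"} models a lung embedded in unbounded interstitium:
#' the outer boundary of the buffer carries an absorbing (Robin) condition
#' \code{-D dc/dn = kappa c} whose impedance is that of an unbounded decaying
#' exterior around the bud (curvature-corrected via modified Bessel
#' functions), so the solution is insensitive to the buffer width. \code{"no_flux"} closes the boundary
#' (zero Neumann) as in the closed-culture comparison runs. The stalk base
#' (y = 0), where the bud is cut from the bronchial tree, is always no-flux.
#' Ptc, which cannot leave the tissue, sees no outer boundary in either case.
#'
#' @param kind One of \code{"open_farfield"}, \code{"no_flux"}.
#' @return Object of class \code{lung_bc}.
#' @export
boundary_condition <- function(kind = c("open_farfield", "no_flux")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "lung_bc")
}

# Absorbing-boundary impedance matrices. The exterior of the buffer is a
# decaying medium; for a radially spreading field the exact impedance of the
# exterior at distance r from the source region is
#   kappa(r) = sqrt(delta * D) * K1(z) / K0(z),  z = r * sqrt(delta / D)
# (modified Bessel functions), which reduces to the planar sqrt(delta * D)
# for z >> 1 but is substantially larger for SHH, whose decay length exceeds
# any practical buffer width. r is measured from the bud mid-stalk.
bc_clist <- function(bc, params, mesh) {
  open <- bc$kind == "open_farfield"
  Ny <- mesh$Ny; Nx <- mesh$Nx
  kx <- matrix(0, Ny, 3)
  ktop <- matrix(0, Nx, 3)
  if (open) {
    half_w <- max(abs(mesh$x)) + mesh$hx / 2
    yc <- (seq_len(Ny) - 0.5) / Ny * mesh$L0
    c0 <- c(0, mesh$h_stalk / 2)
    imped <- function(r, delta, D) {
      z <- pmax(r * sqrt(delta / D), 1e-8)
      sqrt(delta * D) * besselK(z, 1) / besselK(z, 0)
    }
    r_side <- sqrt(half_w^2 + (yc - c0[2])^2)
    r_top <- sqrt(mesh$x^2 + (mesh$L0 - c0[2])^2)
    kx[, 1] <- imped(r_side, params$delta_f, params$D_cavity)
    kx[, 2] <- imped(r_side, params$delta_s, params$D_cavity)
    ktop[, 1] <- imped(r_top, params$delta_f, params$D_cavity)
    ktop[, 2] <- imped(r_top, params$delta_s, params$D_cavity)
  }
  list(open = as.integer(open), kx = kx, ktop = ktop)
}

#' Integrate the reaction-diffusion model
#'
#' Advances the three-species QSSA model (or the four-species model with an
#' explicit SHH-Ptc complex, \code{model = "full"}) from zero initial
#' concentrations plus a small seeded perturbation of FGF10 that breaks the
#' symmetry of the unstable homogeneous state. Time stepping is first-order
#' operator splitting: implicit axis-by-axis diffusion, pointwise
#' backward-Euler kinetics (damped Newton), and, on growing domains,
#' conservative upwind advection with dilution.
#'
#' @param mesh A [make_mesh()] result.
#' @param params A [param_set()].
#' @param t_end End time (dimensionless).
#' @param bc A [boundary_condition()].
#' @param dt Time step.
#' @param model \code{"qssa"} (default) or \code{"full"}; the latter requires
#'   \code{params$kon} and \code{params$koff}.
#' @param growth Optional [growth_spec()]; when given, the stalk elongates
#'   and the PDE gains advection-dilution transport.
#' @param init Optional ncell x 3 (or 4) matrix of initial concentrations;
#'   default all zero.
#' @param perturb_amplitude Amplitude of the uniform random perturbation
#'   added to the initial FGF10 field (set 0 to disable).
#' @param seed RNG seed for the perturbation (reproducibility).
#' @param param_fields Optional ncell x 14 matrix of per-cell multiplicative
#'   parameter perturbations (columns as in the per-label parameter table);
#'   used by the spatial-noise robustness experiments.
#' @param record_every Recording interval in time units.
#' @param steady_tol Steady-state tolerance on max |dc/dt|.
#' @param stop_when_steady Stop early once the tolerance is met (fixed
#'   domains only).
#' @param steady_min_t Hold-off time before the steady check may trigger;
#'   guards against the quiet interval after the base profile has formed but
#'   before the seeded Turing mode has grown to finite amplitude.
#' @return An object of class \code{rd_trajectory}: recorded \code{times},
#'   domain heights \code{L}, a list of ncell x nspecies \code{frames}, the
#'   final subdomain labels, steady/failed flags and residual history.
#' @export
integrate_rd <- function(mesh, params, t_end,
                         bc = boundary_condition("open_farfield"),
                         dt = 0.02, model = c("qssa", "full"),
                         growth = NULL, init = NULL,
                         perturb_amplitude = 1e-6, seed = 1L,
                         param_fields = NULL,
                         record_every = 1, steady_tol = 1e-6,
                         stop_when_steady = FALSE, steady_min_t = 40) {
  stopifnot(inherits(mesh, "lung_mesh"), inherits(params, "lung_params"),
            inherits(bc, "lung_bc"))
  model <- match.arg(model)
  if (model == "full" && (is.null(params$kon) || is.null(params$koff)))
    stop("model = 'full' requires kon and koff in the parameter set", call. = FALSE)
  if (!(t_end > 0) || !(dt > 0)) stop("t_end and dt must be > 0", call. = FALSE)

  nc <- mesh$Nx * mesh$Ny
  nsteps <- as.integer(ceiling(t_end / dt - 1e-9))
  nsp <- if (model == "full") 4L else 3L
  if (is.null(init)) init <- matrix(0, nc, nsp)
  init <- as.matrix(init)
  if (ncol(init) < nsp) init <- cbind(init, matrix(0, nc, nsp - ncol(init)))
  if (nrow(init) != nc) stop("init has wrong number of cells", call. = FALSE)
  if (perturb_amplitude > 0) {
    set.seed(seed)
    init[, 1] <- init[, 1] + perturb_amplitude * stats::runif(nc)
  }

  gl <- growth_schedule(growth, mesh, nsteps, dt)
  if (!is.null(param_fields)) {
    param_fields <- as.matrix(param_fields)
    stopifnot(nrow(param_fields) == nc, ncol(param_fields) == 14)
  }

  kin <- list(n = params$n, nS = params$nS, mP = params$mP,
              full = model == "full",
              kon = if (is.null(params$kon)) 0 else params$kon,
              koff = if (is.null(params$koff)) 0 else params$koff)
  tim <- list(dt = dt, nsteps = nsteps,
              record_every = max(1L, as.integer(round(record_every / dt))),
              steady_tol = steady_tol,
              check_every = max(1L, as.integer(round(1 / dt))),
              stop_when_steady = stop_when_steady, steady_min_t = steady_min_t)

  tab <- par_table(params)
  if (bc$kind == "no_flux") tab[c(1, 4), c("Df", "Ds")] <- 0
  res <- rd_run(mesh$x, mesh$hx, mesh$Ny, mesh$h_stalk, geom_clist(mesh$geometry),
                tab, param_fields, kin, bc_clist(bc, params, mesh),
                tim, gl, init)
  if (res$failed)
    stop("reaction-diffusion integration failed (non-finite fields or kinetics Newton breakdown); try a smaller dt",
         call. = FALSE)
  structure(list(times = res$times, L = res$L, frames = res$frames,
                 labels = res$labels, h_stalk = res$h_stalk,
                 steady = res$steady, steps = res$steps,
                 resid_times = res$resid_times, resid = res$resid,
                 mesh = mesh, params = params, bc = bc, growth = growth,
                 model = model, dt = dt, seed = seed),
            class = "rd_trajectory")
}

#' @export
print.rd_trajectory <- function(x, ...) {
  cat(sprintf("rd_trajectory: %d frames to t = %g (dt = %g), height %g -> %g\n",
              length(x$times), max(x$times), x$dt, x$L[1], x$L[length(x$L)]))
  cat(sprintf("  model %s, %s, steady: %s\n", x$model, x$bc$kind, x$steady))
  invisible(x)
}

#' Extract one species of one frame as an Nx x Ny matrix
#'
#' @param traj An [integrate_rd()] trajectory.
#' @param species One of \code{"f"}, \code{"s"}, \code{"p"}, \code{"c"}.
#' @param frame Frame index (default: last).
#' @return Numeric matrix (columns = axial index).
#' @export
field_matrix <- function(traj, species = "f", frame = length(traj$frames)) {
  sp <- match(species, c("f", "s", "p", "c"))
  if (is.na(sp)) stop("unknown species", call. = FALSE)
  fr <- traj$frames[[frame]]
  matrix(fr[, sp], traj$mesh$Nx, traj$mesh$Ny)
}

# subdomain labels at a given frame (stalk length changes on growing domains)
frame_labels <- function(traj, frame = length(traj$frames)) {
  L <- traj$L[frame]
  m <- traj$mesh
  h <- m$h_stalk + (L - m$L0)
  xi <- (seq_len(m$Ny) - 0.5) / m$Ny
  rd_labels(m$x, xi * L, h, geom_clist(m$geometry))
}

#' Run the model to steady state
#'
#' Integrates until the maximum rate of change of any species falls below
#' \code{tol} (checked on unit-time windows) or \code{t_max} is reached.
#' Non-convergence is reported in the \code{steady} flag, not as an error.
#'
#' @inheritParams integrate_rd
#' @param tol Steady-state tolerance on max |dc/dt| (dimensionless
#'   concentration per unit time).
#' @param t_max Maximum integration time.
#' @param ... Further arguments to [integrate_rd()].
#' @return A \code{solve_report}: final state, trajectory, steady flag,
#'   residual history, wall time, mesh resolution and a config hash.
#' @export
run_to_steady <- function(mesh, params, bc = boundary_condition("open_farfield"),
                          tol = 1e-6, t_max = 200, record_every = 10, ...) {
  t0 <- proc.time()[["elapsed"]]
  traj <- integrate_rd(mesh, params, t_end = t_max, bc = bc,
                       steady_tol = tol, stop_when_steady = TRUE,
                       record_every = record_every, ...)
  structure(list(
    state = traj$frames[[length(traj$frames)]],
    trajectory = traj,
    steady = traj$steady,
    resid_times = traj$resid_times, resid = traj$resid,
    walltime = proc.time()[["elapsed"]] - t0,
    hmax = mesh$hmax,
    config_hash = config_hash(list(geometry = unclass(mesh$geometry),
                                   hmax = mesh$hmax,
                                   params = unclass(params), bc = bc$kind,
                                   tol = tol, t_max = t_max))),
    class = "solve_report")
}

#' @export
print.solve_report <- function(x, ...) {
  cat(sprintf("solve_report: steady = %s (final residual %.3g), %.2f s wall, hmax %g\n",
              x$steady, if (length(x$resid)) tail(x$resid, 1) else NA,
              x$walltime, x$hmax))
  cat("  config", x$config_hash, "\n")
  invisible(x)
}

#' Hash of a configuration object
#'
#' MD5 digest of the canonical serialization; used to stamp outputs for
#' provenance.
#'
#' @param x Any serializable R object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version-pinned serialization so hashes are stable across R versions
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
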
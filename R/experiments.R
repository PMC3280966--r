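#' One-at-a-time parameter sensitivity scan
#'
#' Perturbs each dimensionless parameter independently by the given fold
#' factors, solves the fixed-domain problem to steady state and classifies
#' the FGF10 pattern. With \code{refine}, the factor at which the class first
#' changes is bisected (on a log scale) to 10% accuracy, matching the
#' resolution of the published scan.
#'
#' @param params Reference [param_set()] (its class at factor 1 is the
#'   reference class).
#' @param mesh A [make_mesh()] result.
#' @param factors Fold-change grid; must contain 1.
#' @param param_names Parameters to scan (default: all kinetic/transport
#'   parameters).
#' @param bc,t_max,tol,... Passed to [run_to_steady()].
#' @param refine Bisect class-switch boundaries to 10% factor accuracy.
#' @return Object of class \code{scan_result}: a data.frame (parameter,
#'   factor, class) plus the per-parameter switch boundaries.
#' @export
sensitivity_scan <- function(params, mesh,
                             factors = c(0.5, 0.7, 0.8, 0.9, 1, 1.1, 1.2, 1.3, 1.5, 2),
                             param_names = NULL,
                             bc = boundary_condition("open_farfield"),
                             t_max = 150, tol = 1e-5, refine = FALSE, ...) {
  stopifnot(1 %in% factors)
  if (is.null(param_names))
    param_names <- setdiff(kinetic_param_names(), c("Kf", "Ks", "gamma"))
  classify_at <- function(p) {
    rep <- run_to_steady(mesh, p, bc = bc, t_max = t_max, tol = tol, ...)
    if (!rep$steady) return("unresolved")
    pattern_report(rep$trajectory)$class
  }
  ref_class <- classify_at(params)
  rows <- list()
  bounds <- list()
  for (nm in param_names) {
    cls <- character(length(factors))
    for (i in seq_along(factors)) {
      fa <- factors[i]
      cls[i] <- if (fa == 1) ref_class else
        classify_at(scale_params(params, stats::setNames(fa, nm)))
    }
    rows[[nm]] <- data.frame(parameter = nm, factor = factors, class = cls)
    # nearest class switch on each side of 1, optionally bisected
    sw <- c(lower = NA_real_, upper = NA_real_)
    for (side in c("lower", "upper")) {
      f_side <- if (side == "lower") rev(factors[factors <= 1]) else factors[factors >= 1]
      c_side <- cls[match(f_side, factors)]
      i_sw <- which(c_side != ref_class)[1]
      if (!is.na(i_sw)) {
        f_in <- f_side[i_sw - 1]; f_out <- f_side[i_sw]
        if (refine) {
          while (abs(f_out / f_in - 1) > 0.1 && abs(f_in / f_out - 1) > 0.1) {
            f_mid <- sqrt(f_in * f_out)
            c_mid <- classify_at(scale_params(params, stats::setNames(f_mid, nm)))
            if (c_mid == ref_class) f_in <- f_mid else f_out <- f_mid
          }
        }
        sw[side] <- f_out
      }
    }
    bounds[[nm]] <- sw
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 reference_class = ref_class,
                 switch_bounds = do.call(rbind, bounds)),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Sensitivity scan; reference class:", x$reference_class, "\n")
  print(x$switch_bounds)
  invisible(x)
}

#' Smoothed Gaussian random multiplier field
#'
#' Nodal i.i.d. Gaussian noise smoothed with a separable Gaussian kernel of
#' length \code{ell} and rescaled to standard deviation \code{sd} (pure nodal
#' white noise would be mesh-dependent). Returned as \code{1 + xi}, clipped
#' below at \code{clip} so parameters stay positive.
#'
#' @param mesh A [make_mesh()] result.
#' @param sd Standard deviation of the relative perturbation.
#' @param ell Correlation length (dimensionless; default one cell diameter,
#'   0.1).
#' @param clip Lower clip for the multiplier.
#' @return Numeric vector of length ncell.
#' @export
gaussian_random_field <- function(mesh, sd, ell = 0.1, clip = 0.05) {
  Nx <- mesh$Nx; Ny <- mesh$Ny
  z <- matrix(stats::rnorm(Nx * Ny), Nx, Ny)
  if (sd == 0) return(rep(1, Nx * Ny))
  smooth1 <- function(m, h, along) {
    r <- max(1L, ceiling(3 * ell / h))
    kern <- stats::dnorm(seq(-r, r) * h, sd = ell)
    kern <- kern / sum(kern)
    apply(m, along, function(v) {
      n <- length(v)
      vp <- c(rev(v[seq_len(r)]), v, rev(v[n - seq_len(r) + 1]))
      stats::convolve(vp, rev(kern), type = "filter")
    })
  }
  hy <- mesh$L0 / Ny
  z <- t(smooth1(z, mesh$hx, 2))     # along x
  z <- smooth1(z, hy, 1)             # along y (returns transposed)
  z <- t(z)
  z <- z / stats::sd(z) * sd
  pmax(1 + as.vector(z), clip)
}

#' Noise specification for the spatial-robustness experiment
#'
#' Every kinetic parameter is multiplied by an independent random field
#' \code{1 + xi(x)} with zero-mean Gaussian \code{xi} of standard deviation
#' \code{sd} ("half width") and correlation length \code{ell}; geometrical
#' parameters are never varied.
#'
#' @param sd Relative standard deviation of the perturbations.
#' @param ell Correlation length.
#' @param replicates Number of seeded replicates.
#' @param seed Base seed; replicate r uses seed + r.
#' @return Object of class \code{noise_spec}.
#' @export
noise_spec <- function(sd, ell = 0.1, replicates = 10, seed = 1) {
  stopifnot(sd >= 0, ell > 0, replicates >= 1)
  structure(list(sd = sd, ell = ell, replicates = replicates, seed = seed),
            class = "noise_spec")
}

#' Robustness of the growing-domain pattern to spatial parameter noise
#'
#' Runs the tip-growth lateral-branching protocol with every kinetic
#' parameter perturbed by an independent Gaussian random field (one field per
#' parameter per replicate) and reports the fraction of replicates whose
#' final pattern retains the reference class. Failed runs count as
#' non-preserving.
#'
#' @param params Reference [param_set()].
#' @param mesh Mesh built with \code{final_height} covering the run.
#' @param spec A [noise_spec()].
#' @param growth Growth protocol (default: fast tip growth).
#' @param t_end Run duration.
#' @param reference_class Class counted as preserved.
#' @param ... Passed to [grow_and_solve()].
#' @return List with \code{fraction}, per-replicate table and the spec.
#' @export
noise_robustness <- function(params, mesh, spec,
                             growth = growth_spec("tip", v = 14 / 180),
                             t_end = 60, reference_class = "lateral", ...) {
  stopifnot(inherits(spec, "noise_spec"))
  nc <- mesh$Nx * mesh$Ny
  rows <- lapply(seq_len(spec$replicates), function(r) {
    seed_r <- spec$seed + r
    set.seed(seed_r)
    mult <- matrix(1, nc, 14)
    if (spec$sd > 0)
      for (j in seq_len(14))
        mult[, j] <- gaussian_random_field(mesh, spec$sd, spec$ell)
    cls <- tryCatch({
      traj <- grow_and_solve(mesh, params, growth, t_end = t_end,
                             param_fields = mult, seed = seed_r, ...)
      pattern_report(traj)$class
    }, error = function(e) "failed")
    data.frame(replicate = r, seed = seed_r, class = cls,
               preserved = cls == reference_class)
  })
  tab <- do.call(rbind, rows)
  list(fraction = mean(tab$preserved), table = tab, spec = spec)
}

#' Mutant scenario suite
#'
#' Reproduces the mutant comparisons: (i) FGF10 hypomorph (nu_f x 0.75),
#' fewer/wider-spaced branch points than wild type; (ii) enhanced SHH
#' diffusion (Ds x 2, x 6), gradually increasing spacing; (iii) an SHH
#' expression series, Ptc onset time decreasing with nu_s; (iv) Ptc
#' over-expression (rho0, rho1 scaled up), maximum SHH and effective Ptc
#' production decreasing; (v) loss of pattern under strong SHH gain /
#' FGF10 loss (the retinoic-acid scenario).
#'
#' @param params Reference [param_set()].
#' @param mesh Fixed-domain mesh.
#' @param growth_mesh Mesh for the growing runs (with \code{final_height}).
#' @param growth Growth protocol for spacing/onset scenarios.
#' @param t_grow Duration of growing runs; default grows the stalk by 8
#'   lumen radii, long enough for several branch generations.
#' @param nu_s_series SHH production rates for the onset series.
#' @param rho_factors Ptc production scale factors for scenario (iv).
#' @param scenarios Subset of \code{c("fgf10", "shh_diffusion", "ptc_onset",
#'   "ptc_production", "loss")} to run.
#' @param ... Passed to the solvers.
#' @return Named list of per-scenario data.frames.
#' @export
mutant_suite <- function(params, mesh, growth_mesh = mesh,
                         growth = growth_spec("tip", v = 14 / 180),
                         t_grow = 8 / growth$v,
                         nu_s_series = c(200, 300, 400, 500, 700, 900, 1300, 1700),
                         rho_factors = c(1, 2, 4),
                         scenarios = c("fgf10", "shh_diffusion", "ptc_onset",
                                       "ptc_production", "loss"),
                         ...) {
  out <- list()
  grow_metrics <- function(p) {
    traj <- grow_and_solve(growth_mesh, p, growth, t_end = t_grow, ...)
    rep <- pattern_report(traj)
    sp <- axial_spacing(rep$spots)
    data.frame(class = rep$class, n_spots = nrow(rep$spots),
               mean_gap = if (is.null(sp)) NA_real_ else sp$mean)
  }
  if ("fgf10" %in% scenarios) {
    wt <- grow_metrics(params)
    mu <- grow_metrics(scale_params(params, c(nu_f = 0.75)))
    out$fgf10 <- cbind(data.frame(genotype = c("wildtype", "nu_f x 0.75")),
                       rbind(wt, mu))
  }
  if ("shh_diffusion" %in% scenarios) {
    rows <- lapply(c(1, 2, 6), function(fac)
      cbind(data.frame(Ds_factor = fac),
            grow_metrics(scale_params(params, c(Ds = fac)))))
    out$shh_diffusion <- do.call(rbind, rows)
  }
  if ("ptc_onset" %in% scenarios) {
    basal <- params$rho0 / params$delta_p
    rows <- lapply(nu_s_series, function(ns) {
      p <- params; p$nu_s <- ns
      traj <- grow_and_solve(growth_mesh, p, growth, t_end = max(t_grow, 120),
                             record_every = 1, ...)
      onset <- ptc_onset_time(traj, threshold = 2 * basal)
      data.frame(nu_s = ns, onset_time = onset)
    })
    out$ptc_onset <- do.call(rbind, rows)
  }
  if ("ptc_production" %in% scenarios) {
    rows <- lapply(rho_factors, function(fac) {
      p <- scale_params(params, c(rho0 = fac, rho1 = fac))
      rep <- run_to_steady(mesh, p, ...)
      fr <- rep$state
      lab <- as.vector(rep$trajectory$labels)
      mes <- lab == 3
      cc <- qssa_complex(fr[mes, 2], fr[mes, 3], p$gamma, p$nS, p$mP)
      data.frame(rho_factor = fac,
                 max_shh = max(fr[, 2]),
                 eff_ptc_production = mean(p$rho0 + p$rho1 * cc))
    })
    out$ptc_production <- do.call(rbind, rows)
  }
  if ("loss" %in% scenarios) {
    rows <- lapply(list(c(nu_s = 10), c(nu_f = 0.1), c(nu_s = 10, nu_f = 0.25)),
                   function(fac) {
      rep <- run_to_steady(mesh, scale_params(params, fac), ...)
      data.frame(perturbation = paste(names(fac), "x", fac, collapse = ", "),
                 class = pattern_report(rep$trajectory)$class)
    })
    out$loss <- do.call(rbind, rows)
  }
  out
}

#' First time mesenchymal Ptc exceeds a threshold
#'
#' Onset ("emergence") of Ptc expression, defined as the first recorded time
#' at which the maximum mesenchymal Ptc concentration exceeds
#' \code{threshold} (default twice the basal level rho0/delta_p).
#'
#' @param traj An \code{rd_trajectory}.
#' @param threshold Concentration threshold.
#' @return Time of onset, or NA if never reached.
#' @export
ptc_onset_time <- function(traj, threshold = NULL) {
  if (is.null(threshold))
    threshold <- 2 * traj$params$rho0 / traj$params$delta_p
  for (i in seq_along(traj$frames)) {
    lab <- as.vector(frame_labels(traj, i))
    pm <- traj$frames[[i]][lab == 3, 3]
    if (length(pm) && max(pm) > threshold) return(traj$times[i])
  }
  NA_real_
}

#' Mesenchyme-free (constant-FGF10) culture experiment
#'
#' Freezes FGF10 at a constant value (no production, decay or net transport
#' of a uniform field), so the SHH-Ptc module runs as an effective
#' two-species Schnakenberg system, and reports the pattern class per FGF10
#' level together with the Turing verdict of the frozen-f dispersion.
#'
#' @param f_const Vector of frozen FGF10 concentrations.
#' @param params Reference [param_set()].
#' @param mesh Mesh for the culture domain.
#' @param t_max,... Passed to [run_to_steady()].
#' @return data.frame with f_const, simulated class, number of SHH/Ptc-driven
#'   FGF10... (here: Ptc spots), and the linear Turing verdict.
#' @export
mesenchyme_free <- function(f_const, params, mesh, t_max = 150, ...) {
  rows <- lapply(f_const, function(fc) {
    p <- params
    p$nu_f <- 0; p$delta_f <- 0
    nc <- mesh$Nx * mesh$Ny
    # seed the perturbation in SHH: the frozen FGF10 field must stay uniform
    set.seed(7)
    init <- cbind(rep(fc, nc), 1e-6 * stats::runif(nc), 0)
    rep <- run_to_steady(mesh, p, init = init, perturb_amplitude = 0,
                         t_max = t_max, ...)
    fr <- rep$state
    lab <- as.vector(rep$trajectory$labels)
    mes <- lab == 3
    pvar <- if (any(mes)) stats::sd(fr[mes, 3]) / max(mean(fr[mes, 3]), 1e-12) else 0
    basal <- if (p$delta_p > 0) p$rho0 / p$delta_p else 0
    patterned_sim <- is.finite(pvar) && pvar > 0.2 && max(fr[mes, 3]) > 2 * basal
    ss <- uniform_steady_state(p, freeze_f = TRUE, f_const = fc)
    tur <- if (nrow(ss)) dispersion(p, ss[1, ], freeze_f = TRUE)$turing else FALSE
    data.frame(f_const = fc, patterned = patterned_sim, turing = tur,
               max_ptc = max(fr[, 3]), cv_ptc = pvar)
  })
  do.call(rbind, rows)
}
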
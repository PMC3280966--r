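#' Dimensionless kinetic and transport parameters
#'
#' Collects the dimensionless parameters of the FGF10 (f) / SHH (s) / Ptc (p)
#' reaction-diffusion model. Lengths are in units of the lumen radius and time
#' in units of the FGF10 diffusion time (see [lung_scales()]); FGF10 is scaled
#' by the Hill constant of its activation of SHH and the SHH/Ptc scales absorb
#' the repression Hill constant and the effective binding constant, so
#' \code{Kf}, \code{Ks} and \code{gamma} default to 1.
#'
#' Production is compartment-gated: FGF10 (\code{nu_f}) and Ptc
#' (\code{rho0}, \code{rho1}) are produced in the mesenchyme, SHH (\code{nu_s})
#' in the epithelium. \code{Df}/\code{Ds} take the fast cavity value
#' \code{D_cavity} in lumen and interstitium; the membrane-bound receptor Ptc
#' does not enter the cavities (\code{Dp = 0} there, production and complex
#' turnover restricted to tissue).
#'
#' @param Df,Ds,Dp Tissue diffusivities of FGF10, SHH and Ptc.
#' @param D_cavity Cavity (lumen/interstitium) diffusivity of FGF10 and SHH.
#' @param nu_f,nu_s Maximal FGF10 / SHH production rates.
#' @param rho0,rho1 Zero- and first-order Ptc production rate constants
#'   (production rho0 + rho1 * c).
#' @param delta_f,delta_s,delta_p,delta_c Linear decay rates of FGF10, SHH,
#'   Ptc and the SHH-Ptc complex.
#' @param gamma Effective binding constant of the quasi-steady-state complex,
#'   c = gamma * s^nS * p^mP.
#' @param Kf Hill constant of FGF10 repression by the complex.
#' @param Ks Hill constant of SHH activation by FGF10.
#' @param n Hill coefficient (cooperativity) of both Hill functions.
#' @param nS,mP Stoichiometry of the SHH-Ptc complex (nS SHH per mP Ptc);
#'   patterning requires mP >= 2 (or nS >= 2).
#' @param kon,koff Binding/unbinding rates of the explicit (non-QSSA)
#'   four-species model; only used by [integrate_rd()] with
#'   \code{model = "full"}.
#' @return An object of class \code{lung_params}.
#' @seealso [reference_params()] for the calibrated reference point.
#' @export
param_set <- function(Df = 1, Ds = 5, Dp = 0.02, D_cavity = 40,
                      nu_f = 5, nu_s = 1600,
                      rho0 = 0.6, rho1 = 3.5,
                      delta_f = 5, delta_s = 0.2, delta_p = 1.6, delta_c = 1,
                      gamma = 1, Kf = 1, Ks = 1,
                      n = 2L, nS = 1L, mP = 2L,
                      kon = NULL, koff = NULL) {
  p <- list(Df = Df, Ds = Ds, Dp = Dp, D_cavity = D_cavity,
            nu_f = nu_f, nu_s = nu_s, rho0 = rho0, rho1 = rho1,
            delta_f = delta_f, delta_s = delta_s, delta_p = delta_p,
            delta_c = delta_c, gamma = gamma, Kf = Kf, Ks = Ks,
            n = as.integer(n), nS = as.integer(nS), mP = as.integer(mP),
            kon = kon, koff = koff)
  class(p) <- "lung_params"
  validate_params(p)
  p
}

# names of the scannable kinetic parameters (rates/constants, not exponents)
kinetic_param_names <- function() {
  c("Df", "Ds", "Dp", "D_cavity", "nu_f", "nu_s", "rho0", "rho1",
    "delta_f", "delta_s", "delta_p", "delta_c", "gamma", "Kf", "Ks")
}

validate_params <- function(p) {
  num <- kinetic_param_names()
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop(sprintf("parameter error: %s must be a single non-negative number", nm),
           call. = FALSE)
  }
  if (p$n < 1) stop("parameter error: Hill coefficient n must be >= 1", call. = FALSE)
  if (p$nS < 1 || p$mP < 1)
    stop("parameter error: stoichiometry exponents must be >= 1", call. = FALSE)
  if (p$mP < 2 && p$nS < 2)
    warning("stoichiometry nS = mP = 1 lies outside the Turing-patterning regime",
            call. = FALSE)
  if (p$D_cavity < max(p$Df, p$Ds))
    stop("parameter error: cavity diffusivity must be >= tissue diffusivities",
         call. = FALSE)
  invisible(p)
}

#' Calibrated reference parameter set
#'
#' The dimensionless reference point used for all wild-type simulations. The
#' printed value multiset is fixed; the assignment of values to rate names was
#' calibrated (see the methods vignette) so that the spatially homogeneous
#' steady state is Turing-unstable with a fastest-growing wavelength of about
#' two lumen radii and the fixed-domain simulation yields the lateral
#' branching pattern (tip plus flank FGF10 maxima).
#'
#' @return A [param_set()] at the calibrated reference values.
#' @export
reference_params <- function() param_set()

#' Parameter point of the bifurcation-mode pattern
#'
#' The documented variant of the reference point whose fixed-domain steady
#' state shows FGF10 maxima at the sides of the tip but not the tip itself
#' (the bifurcation branching mode): the receptor decay rate halved,
#' \code{delta_p x 0.5}. Slower receptor turnover raises Ptc and hence
#' SHH-Ptc complex levels around the cap, and the stronger FGF10 repression
#' extinguishes the tip maximum while the side maxima survive. See the
#' methods vignette for how the variant was identified.
#'
#' @return A [param_set()].
#' @export
bifurcation_params <- function() {
  scale_params(reference_params(), c(delta_p = 0.5))
}

#' @export
print.lung_params <- function(x, ...) {
  cat("Dimensionless lung-branching parameters\n")
  cat(sprintf("  D (tissue): f %g, s %g, p %g; cavities %g\n", x$Df, x$Ds, x$Dp, x$D_cavity))
  cat(sprintf("  production: nu_f %g (mes), nu_s %g (epi), Ptc %g + %g c (mes)\n",
              x$nu_f, x$nu_s, x$rho0, x$rho1))
  cat(sprintf("  decay: f %g, s %g, p %g, complex %g\n",
              x$delta_f, x$delta_s, x$delta_p, x$delta_c))
  cat(sprintf("  Hill n = %d, complex = gamma s^%d p^%d (gamma %g), Kf %g, Ks %g\n",
              x$n, x$nS, x$mP, x$gamma, x$Kf, x$Ks))
  invisible(x)
}

#' Multiply selected parameters by fold-change factors
#'
#' @param params A [param_set()].
#' @param factors Named numeric vector of fold changes, e.g.
#'   \code{c(nu_f = 0.75)}.
#' @return A new validated \code{lung_params}.
#' @export
scale_params <- function(params, factors) {
  stopifnot(inherits(params, "lung_params"))
  bad <- setdiff(names(factors), kinetic_param_names())
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (nm in names(factors)) params[[nm]] <- params[[nm]] * factors[[nm]]
  validate_params(params)
  params
}

# 4 x 14 per-label table consumed by the C++ core.
# Label rows: 1 lumen, 2 epithelium, 3 mesenchyme, 4 buffer.
par_table <- function(p) {
  tab <- rbind(
    lumen      = c(p$D_cavity, p$D_cavity, 0,    0,      0,      0,      0,
                   p$delta_f, p$delta_s, 0,         0,          p$gamma, p$Kf, p$Ks),
    epithelium = c(p$Df,       p$Ds,      p$Dp, 0,      p$nu_s, 0,      0,
                   p$delta_f, p$delta_s, p$delta_p, p$delta_c, p$gamma, p$Kf, p$Ks),
    mesenchyme = c(p$Df,       p$Ds,      p$Dp, p$nu_f, 0,      p$rho0, p$rho1,
                   p$delta_f, p$delta_s, p$delta_p, p$delta_c, p$gamma, p$Kf, p$Ks),
    buffer     = c(p$D_cavity, p$D_cavity, 0,   0,      0,      0,      0,
                   p$delta_f, p$delta_s, 0,         0,          p$gamma, p$Kf, p$Ks))
  colnames(tab) <- c("Df", "Ds", "Dp", "nu_f", "nu_s", "rho0", "rho1",
                     "delta_f", "delta_s", "delta_p", "delta_c", "gamma",
                     "Kf", "Ks")
  tab
}

#' Characteristic dimensional scales
#'
#' The model is nondimensionalized with the lumen radius as length unit and
#' the FGF10 diffusion time as time unit. With rc = 50 um and a dimensional
#' FGF10 tissue diffusivity of 2.5 um^2/s the time unit is
#' T = rc^2 / D_F = 1000 s.
#'
#' @param L_um Length unit in micrometres.
#' @param T_s Time unit in seconds.
#' @return Object of class \code{lung_scales}.
#' @export
lung_scales <- function(L_um = 50, T_s = 1000) {
  stopifnot(L_um > 0, T_s > 0)
  structure(list(L_um = L_um, T_s = T_s), class = "lung_scales")
}

#' Convert dimensionless parameters to dimensional units
#'
#' Diffusivities map as D * L^2 / T (um^2/s), rates as rate / T (1/s) and
#' speeds as v * L / T (um/s, also reported per hour).
#'
#' @param params A [param_set()].
#' @param scales A [lung_scales()].
#' @return A data.frame with columns parameter, dimensionless, dimensional,
#'   units.
#' @export
redimensionalize <- function(params, scales = lung_scales()) {
  stopifnot(inherits(params, "lung_params"), inherits(scales, "lung_scales"))
  L <- scales$L_um; T <- scales$T_s
  diff_names <- c("Df", "Ds", "Dp", "D_cavity")
  rate_names <- c("nu_f", "nu_s", "rho0", "delta_f", "delta_s", "delta_p",
                  "delta_c")
  rows <- rbind(
    data.frame(parameter = diff_names,
               dimensionless = unlist(params[diff_names]),
               dimensional = unlist(params[diff_names]) * L^2 / T,
               units = "um^2/s"),
    data.frame(parameter = rate_names,
               dimensionless = unlist(params[rate_names]),
               dimensional = unlist(params[rate_names]) / T,
               units = "1/s"))
  rownames(rows) <- NULL
  rows
}

#' Convert a dimensionless axial growth speed to micrometres per hour
#'
#' @param v Dimensionless speed (lumen radii per time unit).
#' @param scales A [lung_scales()].
#' @return Speed in um/h.
#' @export
speed_to_um_per_h <- function(v, scales = lung_scales()) {
  v * scales$L_um / scales$T_s * 3600
}

#' Map the FGF10-frozen model to the classical Schnakenberg system
#'
#' When the FGF10 concentration is held constant (as in mesenchyme-free
#' culture), SHH production proceeds at the constant rate
#' \code{nu_s * hill_activation(f_const)} and the SHH (substrate, v) / Ptc
#' (activator, u) pair reduces to the classical Schnakenberg model
#' u_t = a - u + u^2 v, v_t = b - u^2 v after rescaling time by
#' \code{delta_p}, u by \code{beta = sqrt(delta_c * gamma / delta_p)} and v by
#' \code{alpha = (rho1 - mP * delta_c) * gamma / (delta_p * beta)}. The limit
#' requires the net complex feedback on Ptc to be positive
#' (\code{rho1 > mP * delta_c}) and neglects SHH decay; a non-negligible
#' \code{delta_s} is reported as a warning attribute, not an error.
#'
#' @param params A [param_set()] with nS = 1, mP = 2.
#' @param f_const The frozen FGF10 concentration.
#' @return List with Schnakenberg \code{a}, \code{b}, diffusivities
#'   \code{Du}, \code{Dv} (time rescaled by delta_p), the variable scalings
#'   \code{alpha}, \code{beta}, the time scale factor, and \code{warnings}.
#' @export
schnakenberg_limit <- function(params, f_const) {
  stopifnot(inherits(params, "lung_params"))
  p <- params
  if (p$nS != 1 || p$mP != 2)
    stop("the Schnakenberg limit applies to the reference stoichiometry nS = 1, mP = 2",
         call. = FALSE)
  q <- p$rho1 - p$mP * p$delta_c
  if (q <= 0)
    stop("no Schnakenberg limit: rho1 <= mP * delta_c (no net activator autocatalysis)",
         call. = FALSE)
  warn <- character()
  if (p$delta_s > 0.25 * p$delta_p)
    warn <- c(warn, sprintf(
      "delta_s = %g is not negligible against delta_p = %g; the mapping drops SHH decay",
      p$delta_s, p$delta_p))
  beta <- sqrt(p$delta_c * p$gamma / p$delta_p)
  alpha <- q * p$gamma / (p$delta_p * beta)
  sigma <- p$nu_s * hill_activation(f_const, p$Ks, p$n)
  list(a = beta * p$rho0 / p$delta_p,
       b = alpha * sigma / p$delta_p,
       Du = p$Dp / p$delta_p, Dv = p$Ds / p$delta_p,
       alpha = alpha, beta = beta, time_scale = p$delta_p,
       warnings = warn)
}
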
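#' Idealized lung-bud cross-section geometry
#'
#' Describes the axial 2D slice of an early lung bud used throughout the
#' package: a stalk of lumen radius \code{rc} (the unit of length) capped by a
#' semicircular tip, wrapped by an epithelial layer of thickness \code{we} and
#' a mesenchymal shell of outer radius \code{Rc}, embedded in an interstitial
#' buffer of width \code{Lfar}. The stalk axis is the y axis, the stalk base
#' sits at y = 0 and the lumen cap centre at y = \code{h0}.
#'
#' All lengths are dimensionless, in units of the lumen radius (50 um
#' dimensionally, see [lung_scales()]). Reference values: \code{rc = 1},
#' \code{Rc = 2}, \code{we = 0.2} (a 10 um epithelium).
#'
#' Tip deformations emulate perturbed bud shapes: \code{tip_epithelium_scale}
#' scales the lumen and epithelial radii at the tip, \code{tip_mesenchyme_scale}
#' the mesenchymal radius, both blending linearly into the undeformed stalk
#' over \code{blend_width}; \code{stalk_truncation_fraction} removes that
#' fraction of the stalk length.
#'
#' @param rc Lumen (inner) radius; the length unit, normally 1.
#' @param Rc Outer mesenchyme radius.
#' @param we Epithelium thickness.
#' @param h0 Initial stalk length (lumen cap centre height).
#' @param Lfar Width of the interstitial far-field buffer around the tissue.
#' @param tip_epithelium_scale,tip_mesenchyme_scale Tip radius scale factors.
#' @param stalk_truncation_fraction Fraction of the stalk removed, in [0, 1).
#' @param blend_width Axial width over which tip deformations blend into the
#'   stalk.
#' @return An object of class \code{lung_geometry}.
#' @examples
#' g <- lung_geometry()
#' geometry_areas(g)
#' @export
lung_geometry <- function(rc = 1, Rc = 2, we = 0.2, h0 = 2, Lfar = 2,
                          tip_epithelium_scale = 1,
                          tip_mesenchyme_scale = 1,
                          stalk_truncation_fraction = 0,
                          blend_width = 1) {
  g <- list(rc = rc, Rc = Rc, we = we, h0 = h0, Lfar = Lfar,
            tip_epithelium_scale = tip_epithelium_scale,
            tip_mesenchyme_scale = tip_mesenchyme_scale,
            stalk_truncation_fraction = stalk_truncation_fraction,
            blend_width = blend_width)
  class(g) <- "lung_geometry"
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  stopifnot(is.numeric(g$rc), is.numeric(g$Rc), is.numeric(g$we))
  if (!(g$rc > 0)) stop("geometry error: rc must be > 0", call. = FALSE)
  if (!(g$we > 0)) stop("geometry error: we must be > 0 (degenerate epithelium)",
                        call. = FALSE)
  if (!(g$rc < g$rc + g$we))
    stop("geometry error: rc < rc + we violated", call. = FALSE)
  if (!(g$rc + g$we < g$Rc))
    stop("geometry error: rc + we < Rc violated", call. = FALSE)
  if (!(g$Lfar > 0))
    stop("geometry error: Rc < Rc + Lfar violated (Lfar must be > 0)", call. = FALSE)
  if (g$h0 < 0) stop("geometry error: h0 must be >= 0", call. = FALSE)
  se <- g$tip_epithelium_scale; sm <- g$tip_mesenchyme_scale
  if (se <= 0 || sm <= 0)
    stop("geometry error: deformation scales must be > 0", call. = FALSE)
  if ((g$rc + g$we) * se >= g$Rc * sm)
    stop("geometry error: deformed tip epithelium reaches the mesenchyme edge (rc + we < Rc violated at the tip)",
         call. = FALSE)
  if (g$stalk_truncation_fraction < 0 || g$stalk_truncation_fraction >= 1)
    stop("geometry error: stalk_truncation_fraction must be in [0, 1)", call. = FALSE)
  invisible(g)
}

#' @export
print.lung_geometry <- function(x, ...) {
  cat("Lung-bud cross-section geometry (units of rc)\n")
  cat(sprintf("  lumen radius rc = %g, epithelium we = %g, mesenchyme Rc = %g\n",
              x$rc, x$we, x$Rc))
  cat(sprintf("  stalk length h0 = %g (truncation %g), buffer Lfar = %g\n",
              effective_stalk(x), x$stalk_truncation_fraction, x$Lfar))
  if (x$tip_epithelium_scale != 1 || x$tip_mesenchyme_scale != 1)
    cat(sprintf("  tip deformation: epithelium x%g, mesenchyme x%g\n",
                x$tip_epithelium_scale, x$tip_mesenchyme_scale))
  invisible(x)
}

# stalk length after truncation
effective_stalk <- function(g) g$h0 * (1 - g$stalk_truncation_fraction)

#' Apply a tip or stalk deformation to a geometry
#'
#' Deformations follow the robustness protocols used for the fixed-domain
#' simulations: a tip epithelial radius increased by 25%
#' (\code{tip_epithelium_scale = 1.25}), a tip mesenchymal radius increased by
#' 10% (\code{tip_mesenchyme_scale = 1.1}), or a stalk truncated by 80%
#' (\code{stalk_truncation_fraction = 0.8}).
#'
#' @param geometry A [lung_geometry()].
#' @param tip_epithelium_scale,tip_mesenchyme_scale,stalk_truncation_fraction
#'   Deformation parameters; defaults leave the geometry unchanged.
#' @return A new validated \code{lung_geometry}.
#' @examples
#' g <- apply_deformation(lung_geometry(), stalk_truncation_fraction = 0.8)
#' @export
apply_deformation <- function(geometry,
                              tip_epithelium_scale = 1,
                              tip_mesenchyme_scale = 1,
                              stalk_truncation_fraction = 0) {
  stopifnot(inherits(geometry, "lung_geometry"))
  if (tip_epithelium_scale <= 0 || tip_mesenchyme_scale <= 0)
    stop("geometry error: deformation scales must be > 0", call. = FALSE)
  g <- geometry
  g$tip_epithelium_scale <- g$tip_epithelium_scale * tip_epithelium_scale
  g$tip_mesenchyme_scale <- g$tip_mesenchyme_scale * tip_mesenchyme_scale
  g$stalk_truncation_fraction <-
    1 - (1 - g$stalk_truncation_fraction) * (1 - stalk_truncation_fraction)
  validate_geometry(g)
  g
}

#' Closed-form subdomain areas of the undeformed geometry
#'
#' For the reference shape (no tip deformation) each tissue subdomain is a
#' pair of stalk rectangles plus a half-annulus over the cap, so the areas
#' have elementary closed forms; used as the analytic oracle for mesh
#' convergence checks.
#'
#' @param geometry A [lung_geometry()] without tip deformations.
#' @return Named vector with lumen, epithelium and mesenchyme areas.
#' @export
geometry_areas <- function(geometry) {
  g <- geometry
  if (g$tip_epithelium_scale != 1 || g$tip_mesenchyme_scale != 1)
    stop("closed-form areas are only available for undeformed tips", call. = FALSE)
  h <- effective_stalk(g)
  re <- g$rc + g$we
  c(lumen = 2 * g$rc * h + pi / 2 * g$rc^2,
    epithelium = 2 * g$we * h + pi / 2 * (re^2 - g$rc^2),
    mesenchyme = 2 * (g$Rc - re) * h + pi / 2 * (g$Rc^2 - re^2))
}

# list consumed by the C++ label kernel
geom_clist <- function(g) {
  list(rc = g$rc, we = g$we, Rc = g$Rc,
       tip_epithelium_scale = g$tip_epithelium_scale,
       tip_mesenchyme_scale = g$tip_mesenchyme_scale,
       blend_width = g$blend_width,
       cap_off = g$Rc * g$tip_mesenchyme_scale + g$Lfar)
}
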
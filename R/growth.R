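#' Axial growth specification
#'
#' One-dimensional growth of the lung stalk in three modes:
#' \describe{
#'   \item{tip}{new material is added in a tip window of width \code{wtip}
#'     just below the cap, which advances at constant speed \code{v}; the
#'     stalk below the window is at rest. The reference fast speed
#'     \code{v = 14/180} corresponds to 14 um/h.}
#'   \item{uniform}{the whole stalk stretches homogeneously at relative rate
#'     \code{mu}, so the stalk length grows exponentially,
#'     h(t) = h0 exp(mu t); the cap translates rigidly.}
#'   \item{graded}{the axial strain rate in the tip window is \code{ratio}
#'     times the strain rate in the stalk, with the stalk rate chosen at each
#'     instant so the total elongation speed equals \code{v}; ratio = 1
#'     recovers uniform stretching at fixed total speed, large ratios
#'     approach tip growth.}
#' }
#'
#' @param mode Growth mode.
#' @param v Tip elongation speed (dimensionless length/time); tip and graded
#'   modes.
#' @param mu Relative growth rate (1/time); uniform mode.
#' @param ratio Tip-to-stalk strain-rate ratio (>= 1); graded mode.
#' @param wtip Width of the tip growth window.
#' @return Object of class \code{growth_spec}.
#' @export
growth_spec <- function(mode = c("tip", "uniform", "graded"),
                        v = 14 / 180, mu = NULL, ratio = NULL, wtip = 1) {
  mode <- match.arg(mode)
  if (mode == "uniform") {
    if (is.null(mu) || mu < 0) stop("uniform growth needs mu >= 0", call. = FALSE)
  } else {
    if (is.null(v) || v < 0) stop("growth needs speed v >= 0", call. = FALSE)
  }
  if (mode == "graded") {
    if (is.null(ratio) || ratio < 1)
      stop("graded growth needs ratio >= 1", call. = FALSE)
  }
  if (wtip <= 0) stop("wtip must be > 0", call. = FALSE)
  structure(list(mode = mode, v = v, mu = mu, ratio = ratio, wtip = wtip),
            class = "growth_spec")
}

# Per-step growth schedule for the C++ core: domain height L, stalk/tip
# strain rates gs/gt at every step. Heights are prescribed in closed form so
# trajectories are reproducible independent of dt.
growth_schedule <- function(growth, mesh, nsteps, dt) {
  L0 <- mesh$L0
  if (is.null(growth))
    return(list(on = FALSE, L0 = L0))
  stopifnot(inherits(growth, "growth_spec"))
  t_edges <- seq(0, nsteps) * dt
  t_mid <- (seq_len(nsteps) - 0.5) * dt
  h0 <- mesh$h_stalk
  cap_off <- L0 - h0
  w <- growth$wtip
  if (growth$mode == "tip") {
    L <- L0 + growth$v * t_edges
    gs <- rep(0, nsteps)
    gt <- rep(growth$v / w, nsteps)
  } else if (growth$mode == "uniform") {
    h <- h0 * exp(growth$mu * t_edges)
    L <- h + cap_off
    gs <- rep(growth$mu, nsteps)
    gt <- rep(growth$mu, nsteps)
  } else {  # graded: constant total speed v, tip strain = ratio * stalk strain
    L <- L0 + growth$v * t_edges
    h_mid <- h0 + growth$v * t_mid
    gs <- growth$v / (pmax(h_mid - w, 0) + growth$ratio * w)
    gt <- growth$ratio * gs
  }
  Lmax <- max(L)
  if (Lmax / mesh$Ny > 1.6 * mesh$hmax)
    warning(sprintf(
      "mesh resolution degrades to %.3g > 1.6 * hmax at final height %.3g; build the mesh with final_height = %.3g",
      Lmax / mesh$Ny, Lmax, Lmax), call. = FALSE)
  list(on = TRUE, L0 = L0, L = L, gs = gs, gt = gt, wtip = w)
}

#' Stalk height under homogeneous exponential growth
#'
#' Closed form of dh/dt = mu h: \code{h(t) = h0 exp(mu t)}.
#'
#' @param h0 Initial stalk length.
#' @param mu Relative growth rate (1/time).
#' @param t Time (vectorized).
#' @return Stalk length h(t).
#' @export
uniform_growth_height <- function(h0, mu, t) {
  stopifnot(mu >= 0, h0 >= 0)
  h0 * exp(mu * t)
}

#' Grow the domain while solving the model
#'
#' Convenience wrapper around [integrate_rd()] with a [growth_spec()].
#'
#' @inheritParams integrate_rd
#' @param growth A [growth_spec()].
#' @param ... Passed to [integrate_rd()].
#' @return An \code{rd_trajectory}.
#' @export
grow_and_solve <- function(mesh, params, growth, t_end,
                           bc = boundary_condition("open_farfield"), ...) {
  integrate_rd(mesh, params, t_end = t_end, bc = bc, growth = growth, ...)
}

#' Total amount of each species over the domain
#'
#' Integrates each recorded frame over the physical domain (cell area scales
#' with the instantaneous height); under pure growth with reactions off and
#' closed boundaries these integrals are conserved.
#'
#' @param traj An \code{rd_trajectory}.
#' @return data.frame with time, height and one total per species.
#' @export
total_mass <- function(traj) {
  m <- traj$mesh
  out <- lapply(seq_along(traj$frames), function(i) {
    cell <- m$hx * traj$L[i] / m$Ny
    fr <- traj$frames[[i]]
    data.frame(time = traj$times[i], L = traj$L[i],
               f = sum(fr[, 1]) * cell, s = sum(fr[, 2]) * cell,
               p = sum(fr[, 3]) * cell)
  })
  do.call(rbind, out)
}

#' Where do new branch sites appear relative to the tip?
#'
#' Classifies where new FGF10 maxima first appear relative to the advancing
#' tip. The primary classification uses the first event after pattern
#' establishment: \code{"behind_tip"} if it lies within \code{behind_zone}
#' of the stalk top, \code{"proximal"} otherwise, \code{"none"} without
#' events. The full event table and the fraction of behind-tip events are
#' returned for inspection.
#'
#' @param growth The [growth_spec()] used (kept for reporting).
#' @param trajectory An \code{rd_trajectory} from a growing run.
#' @param behind_zone Distance behind the stalk top that counts as
#'   "directly behind the tip" (dimensionless; about one pattern wavelength).
#' @param ... Passed to [branch_events()].
#' @return List with the classification, the event table and the zone used.
#' @export
branch_site_location_mode <- function(growth, trajectory, behind_zone = 2.5, ...) {
  ev <- branch_events(trajectory, ...)
  if (nrow(ev) == 0)
    return(list(mode = "none", events = ev, behind_zone = behind_zone))
  behind <- (ev$tip_y - ev$y) <= behind_zone
  mode <- if (behind[1]) "behind_tip" else "proximal"
  list(mode = mode, events = ev, behind_zone = behind_zone,
       behind_fraction = mean(behind))
}
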
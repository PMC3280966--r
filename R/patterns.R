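#' Detect FGF10 spots (local maxima) in a field
#'
#' Finds grid-local maxima of a scalar field restricted to the mesenchyme,
#' keeps those above \code{theta_rel} times the global mesenchymal maximum,
#' merges maxima closer than \code{r_merge} (keeping the highest) and
#' requires topographic prominence: a maximum only counts as a separate spot
#' if the field dips at least \code{min_prominence} (relative to the lower
#' peak) along the line towards every stronger spot, which suppresses the
#' near-degenerate ripples a discrete plateau produces. All thresholds are
#' relative, so detection is invariant to uniform rescaling of the field.
#'
#' @param field Numeric Nx x Ny matrix (or vector of length Nx * Ny).
#' @param mesh The [make_mesh()] the field lives on.
#' @param L Domain height of the frame (defaults to the mesh's initial
#'   height; pass the frame height for growing domains).
#' @param labels Subdomain labels of the frame (default: the mesh's).
#' @param theta_rel Relative peak threshold in (0, 1).
#' @param r_merge Merge radius (dimensionless).
#' @param min_prominence Minimum relative dip separating two spots.
#' @param tip_halfangle Half-opening angle (degrees) of the tip sector used
#'   to tag spots, measured from the stalk axis at the lumen cap centre.
#' @param shoulder_depth Axial depth below the stalk top still counted as
#'   shoulder.
#' @return data.frame with columns x, y, value, zone (tip/shoulder/flank),
#'   ordered by decreasing value. Zero rows for an all-zero field.
#' @export
detect_spots <- function(field, mesh, L = NULL, labels = NULL,
                         theta_rel = 0.3, r_merge = 0.3,
                         min_prominence = 0.1,
                         tip_halfangle = 45, shoulder_depth = 1) {
  stopifnot(inherits(mesh, "lung_mesh"))
  if (!(theta_rel > 0 && theta_rel < 1)) stop("theta_rel must be in (0,1)", call. = FALSE)
  Nx <- mesh$Nx; Ny <- mesh$Ny
  if (is.null(L)) L <- mesh$L0
  h <- mesh$h_stalk + (L - mesh$L0)
  if (is.null(labels)) {
    xi <- (seq_len(Ny) - 0.5) / Ny
    labels <- rd_labels(mesh$x, xi * L, h, geom_clist(mesh$geometry))
  }
  f <- matrix(field, Nx, Ny)
  if (any(f < -1e-9)) stop("field must be non-negative", call. = FALSE)
  mes <- labels == 3
  if (!any(mes) || max(f[mes]) <= 0)
    return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0),
                      zone = character(0)))
  fmax <- max(f[mes])
  # pad with -Inf and compare against the 8-neighbourhood
  fp <- matrix(-Inf, Nx + 2, Ny + 2)
  fp[2:(Nx + 1), 2:(Ny + 1)] <- f
  ge <- function(di, dj) f >= fp[(2 + di):(Nx + 1 + di), (2 + dj):(Ny + 1 + dj)]
  ismax <- ge(1, 0) & ge(-1, 0) & ge(0, 1) & ge(0, -1) &
           ge(1, 1) & ge(1, -1) & ge(-1, 1) & ge(-1, -1)
  cand <- which(ismax & mes & f >= theta_rel * fmax, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0),
                      zone = character(0)))
  xi <- (seq_len(Ny) - 0.5) / Ny
  px <- mesh$x[cand[, 1]]
  py <- xi[cand[, 2]] * L
  pv <- f[cand]
  o <- order(-pv)
  px <- px[o]; py <- py[o]; pv <- pv[o]
  # nearest-cell field lookup for the prominence line scan
  half_w <- max(abs(mesh$x)) + mesh$hx / 2
  hy <- L / Ny
  fat <- function(qx, qy) {
    i <- pmin(pmax(as.integer(floor((qx + half_w) / mesh$hx)) + 1L, 1L), Nx)
    j <- pmin(pmax(as.integer(floor(qy / hy)) + 1L, 1L), Ny)
    f[cbind(i, j)]
  }
  keep <- logical(length(pv))
  for (i in seq_along(pv)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d <- sqrt((px[i] - px[keep])^2 + (py[i] - py[keep])^2)
    if (any(d <= r_merge)) next
    distinct <- TRUE
    for (k in which(keep)) {
      tt <- seq(0, 1, length.out = 24)
      valley <- min(fat(px[i] + tt * (px[k] - px[i]),
                        py[i] + tt * (py[k] - py[i])))
      if (valley >= (1 - min_prominence) * pv[i]) { distinct <- FALSE; break }
    }
    if (distinct) keep[i] <- TRUE
  }
  px <- px[keep]; py <- py[keep]; pv <- pv[keep]
  ang <- atan2(abs(px), py - h) * 180 / pi       # 0 along the axis above the cap
  zone <- ifelse(py > h & ang <= tip_halfangle, "tip",
                 ifelse(py > h - shoulder_depth, "shoulder", "flank"))
  data.frame(x = px, y = py, value = pv, zone = zone)
}

#' Classify a spot pattern into a branching mode
#'
#' \code{"elongation"}: a tip spot only; \code{"lateral"}: a tip spot plus at
#' least one flank/shoulder spot (new buds along the stalk, domain/lateral
#' branching); \code{"bifurcation"}: shoulder spots beside the tip but no tip
#' spot (the tip splits); \code{"none"}: no spots (or spots only far down the
#' flank without any tip signal, which the taxonomy cannot name).
#'
#' @param spots A [detect_spots()] data.frame.
#' @return Character class.
#' @export
classify_mode <- function(spots) {
  if (nrow(spots) == 0) return("none")
  has_tip <- any(spots$zone == "tip")
  has_other <- any(spots$zone != "tip")
  if (has_tip && has_other) return("lateral")
  if (has_tip) return("elongation")
  if (any(spots$zone == "shoulder")) return("bifurcation")
  "none"
}

#' Classify the final FGF10 pattern of a trajectory
#'
#' @param traj An \code{rd_trajectory}.
#' @param frame Frame index (default last).
#' @param ... Passed to [detect_spots()].
#' @return List with \code{class}, the \code{spots} table, and the detection
#'   settings (reported with every result).
#' @export
pattern_report <- function(traj, frame = length(traj$frames), ...) {
  spots <- detect_spots(field_matrix(traj, "f", frame), traj$mesh,
                        L = traj$L[frame], labels = frame_labels(traj, frame), ...)
  settings <- list(...)
  list(class = classify_mode(spots), spots = spots,
       frame = frame, time = traj$times[frame], settings = settings)
}

#' Axial spacings between branch-point maxima
#'
#' Left/right spot pairs of the 2D slice mark the same branch ring, so spots
#' are first clustered by axial position (within \code{r_merge}); gaps are the
#' differences between consecutive cluster positions.
#'
#' @param spots A [detect_spots()] data.frame with >= 2 spots.
#' @param r_merge Axial clustering tolerance.
#' @return List with sorted axial \code{positions}, \code{gaps}, and their
#'   \code{mean} and \code{min}; NULL if fewer than two distinct positions.
#' @export
axial_spacing <- function(spots, r_merge = 0.3) {
  if (nrow(spots) < 2) return(NULL)
  ys <- sort(spots$y)
  grp <- cumsum(c(1, diff(ys) > r_merge))
  pos <- as.numeric(tapply(ys, grp, mean))
  if (length(pos) < 2) return(NULL)
  gaps <- diff(pos)
  list(positions = pos, gaps = gaps, mean = mean(gaps), min = min(gaps))
}

#' Branch-event timeline of a growing-domain trajectory
#'
#' Tracks FGF10 spots across recorded frames (nearest-neighbour matching
#' within \code{match_radius}, clustering left/right pairs by axial position)
#' and logs a branch event when a new axial spot position appears and
#' persists for at least \code{debounce} of the run duration.
#'
#' @param traj An \code{rd_trajectory}.
#' @param theta_rel,r_merge Passed to [detect_spots()].
#' @param match_radius Axial distance within which a spot is matched to an
#'   existing track.
#' @param debounce Fraction of the run duration a new spot must persist.
#' @param t_min Ignore frames before this time (pattern establishment).
#' Spots present in the first analyzed frame are pre-existing pattern, not
#' events; event positions are where the spot first appeared (spots advect
#' with the growing material afterwards).
#'
#' @return data.frame with one row per event: time and axial position of
#'   first appearance, and the stalk-top position \code{tip_y} at that time.
#' @export
branch_events <- function(traj, theta_rel = 0.3, r_merge = 0.3,
                          match_radius = 0.6, debounce = 0.05, t_min = 0) {
  m <- traj$mesh
  duration <- max(traj$times)
  frames <- which(traj$times >= t_min)
  tracks <- data.frame(y = numeric(0), y0 = numeric(0), t0 = numeric(0),
                       tip0 = numeric(0), last = numeric(0),
                       frames_seen = integer(0), initial = logical(0))
  for (i in frames) {
    L <- traj$L[i]
    h <- m$h_stalk + (L - m$L0)
    sp <- detect_spots(field_matrix(traj, "f", i), m, L = L,
                       labels = frame_labels(traj, i),
                       theta_rel = theta_rel, r_merge = r_merge)
    if (nrow(sp) == 0) next
    ys <- sort(sp$y)
    grp <- cumsum(c(1, diff(ys) > r_merge))
    pos <- as.numeric(tapply(ys, grp, mean))
    for (y in pos) {
      if (nrow(tracks) > 0) {
        d <- abs(tracks$y - y)
        j <- which.min(d)
        if (d[j] <= match_radius) {
          tracks$y[j] <- y
          tracks$last[j] <- traj$times[i]
          tracks$frames_seen[j] <- tracks$frames_seen[j] + 1L
          next
        }
      }
      tracks <- rbind(tracks, data.frame(y = y, y0 = y, t0 = traj$times[i],
                                         tip0 = h, last = traj$times[i],
                                         frames_seen = 1L,
                                         initial = i == frames[1]))
    }
  }
  if (nrow(tracks) == 0)
    return(data.frame(time = numeric(0), y = numeric(0), tip_y = numeric(0)))
  persist <- (tracks$last - tracks$t0) >= debounce * duration |
    tracks$t0 >= max(traj$times) - 2 * debounce * duration  # very late events
  ev <- tracks[persist & tracks$frames_seen >= 2 & !tracks$initial, , drop = FALSE]
  ev <- ev[order(ev$t0), , drop = FALSE]
  data.frame(time = ev$t0, y = ev$y0, tip_y = ev$tip0)
}
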
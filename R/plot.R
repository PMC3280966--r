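#' Plot a concentration field with tissue outlines and detected spots
#'
#' Heat map of one species on the physical domain, with subdomain contours
#' and (optionally) the detected FGF10 maxima overlaid.
#'
#' @param traj An \code{rd_trajectory}.
#' @param species Species to plot.
#' @param frame Frame index (default last).
#' @param spots Optional [detect_spots()] table to overlay.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the plotted matrix.
#' @export
plot_field <- function(traj, species = "f", frame = length(traj$frames),
                       spots = NULL, ...) {
  m <- traj$mesh
  L <- traj$L[frame]
  xi <- (seq_len(m$Ny) - 0.5) / m$Ny
  z <- field_matrix(traj, species, frame)
  graphics::image(m$x, xi * L, z, asp = 1, xlab = "x (rc)", ylab = "y (rc)",
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = sprintf("%s at t = %g", species, traj$times[frame]), ...)
  lab <- frame_labels(traj, frame)
  graphics::contour(m$x, xi * L, (lab == 1) + (lab <= 2) + (lab <= 3),
                    add = TRUE, drawlabels = FALSE, col = "white",
                    levels = c(0.5, 1.5, 2.5))
  if (!is.null(spots) && nrow(spots))
    graphics::points(spots$x, spots$y, pch = 4, cex = 1.4, col = "red", lwd = 2)
  invisible(z)
}
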
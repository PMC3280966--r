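#' Deterministic synthetic fixtures for testing
#'
#' \describe{
#'   \item{gaussian_spots_field}{a reference mesh plus a field made of
#'     Gaussian bumps at known mesenchymal locations (ground truth for spot
#'     detection).}
#'   \item{tiny_mesh}{a very coarse mesh of the reference geometry for fast
#'     solver smoke tests.}
#'   \item{schnakenberg_point}{a textbook Turing-unstable Schnakenberg
#'     parameter point (a, b, Du, Dv).}
#' }
#'
#' @param kind Fixture kind.
#' @param seed RNG seed controlling the random placement.
#' @param n_spots Number of bumps for \code{gaussian_spots_field}.
#' @return A list; contents depend on \code{kind}.
#' @export
make_fixture <- function(kind = c("gaussian_spots_field", "tiny_mesh",
                                  "schnakenberg_point"),
                         seed = 1, n_spots = 3) {
  kind <- match.arg(kind)
  if (kind == "tiny_mesh")
    return(list(mesh = make_mesh(lung_geometry(), hmax = 0.5)))
  if (kind == "schnakenberg_point")
    return(list(a = 0.05, b = 1.2, Du = 1, Dv = 60))
  mesh <- make_mesh(lung_geometry(), hmax = 0.2)
  set.seed(seed)
  cells <- mesh_cells(mesh)
  mes <- cells[cells$label == 3, ]
  # keep bump centres well apart
  centers <- mes[sample(nrow(mes)), c("x", "y")]
  pick <- centers[1, , drop = FALSE]
  i <- 2
  while (nrow(pick) < n_spots && i <= nrow(centers)) {
    d <- sqrt((centers$x[i] - pick$x)^2 + (centers$y[i] - pick$y)^2)
    if (all(d > 1.2)) pick <- rbind(pick, centers[i, ])
    i <- i + 1
  }
  f <- rep(0, nrow(cells))
  for (j in seq_len(nrow(pick)))
    f <- f + exp(-((cells$x - pick$x[j])^2 + (cells$y - pick$y[j])^2) / (2 * 0.15^2))
  list(mesh = mesh, field = matrix(f, mesh$Nx, mesh$Ny),
       centers = pick[order(-pick$y), ])
}
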
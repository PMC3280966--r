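#' Reaction right-hand side of the spatially homogeneous surrogate
#'
#' For linear stability analysis the heterogeneous production pattern is
#' replaced by the homogeneous surrogate in which every production term is
#' active everywhere (as on a closed, well-mixed tissue domain). Optionally
#' the FGF10 equation can be frozen (\code{freeze_f}), which decouples the
#' SHH-Ptc patterning module as in mesenchyme-free culture.
#'
#' @param state Numeric vector (f, s, p).
#' @param params A [param_set()].
#' @param freeze_f Hold f constant (df/dt = 0).
#' @return Numeric vector (df, ds, dp).
#' @export
homogeneous_rhs <- function(state, params, freeze_f = FALSE) {
  p <- params
  f <- state[1]; s <- state[2]; pp <- state[3]
  cc <- qssa_complex(s, pp, p$gamma, p$nS, p$mP)
  df <- if (freeze_f) 0 else p$nu_f * hill_repression(cc, p$Kf, p$n) - p$delta_f * f
  ds <- p$nu_s * hill_activation(f, p$Ks, p$n) - p$delta_s * s - p$delta_c * cc
  dp <- p$rho0 + p$rho1 * cc - p$delta_p * pp - p$mP * p$delta_c * cc
  c(df, ds, dp)
}

#' Jacobian of the homogeneous reaction kinetics
#'
#' @inheritParams homogeneous_rhs
#' @return 3 x 3 Jacobian matrix (rows/cols f, s, p).
#' @export
reaction_jacobian <- function(state, params, freeze_f = FALSE) {
  p <- params
  f <- state[1]; s <- state[2]; pp <- state[3]
  cc <- p$gamma * s^p$nS * pp^p$mP
  dcs <- p$gamma * p$nS * (if (p$nS > 1) s^(p$nS - 1) else 1) * pp^p$mP
  dcp <- p$gamma * s^p$nS * p$mP * (if (p$mP > 1) pp^(p$mP - 1) else 1)
  Kfn <- p$Kf^p$n
  drep <- if (cc > 0) -p$n * cc^(p$n - 1) * Kfn / (Kfn + cc^p$n)^2 else 0
  Ksn <- p$Ks^p$n
  dH <- if (f > 0) p$n * f^(p$n - 1) * Ksn / (Ksn + f^p$n)^2 else
    (if (p$n == 1) 1 / Ksn else 0)
  q <- p$rho1 - p$mP * p$delta_c
  J <- matrix(c(
    -p$delta_f,        p$nu_f * drep * dcs,          p$nu_f * drep * dcp,
    p$nu_s * dH,      -p$delta_s - p$delta_c * dcs, -p$delta_c * dcp,
    0,                 q * dcs,                      q * dcp - p$delta_p),
    3, 3, byrow = TRUE)
  if (freeze_f) J[1, ] <- c(0, 0, 0)
  J
}

#' Spatially uniform steady states of the homogeneous surrogate
#'
#' Multistart damped Newton on [homogeneous_rhs()]; duplicate roots are
#' collapsed, so multiplicity is visible in the number of rows.
#'
#' @param params A [param_set()].
#' @param n_start Number of random starting points.
#' @param seed RNG seed for the starts.
#' @param freeze_f Freeze the FGF10 equation at \code{f_const}.
#' @param f_const Frozen FGF10 value (with \code{freeze_f}).
#' @return Matrix with one row per distinct non-negative root (columns f, s,
#'   p); zero rows if none is found.
#' @export
uniform_steady_state <- function(params, n_start = 80, seed = 1,
                                 freeze_f = FALSE, f_const = NULL) {
  set.seed(seed)
  roots <- list()
  for (i in seq_len(n_start)) {
    x <- 10^stats::runif(3, -3, 3)
    if (freeze_f) x[1] <- f_const
    ok <- FALSE
    for (it in 1:200) {
      r <- homogeneous_rhs(x, params, freeze_f)
      J <- reaction_jacobian(x, params, freeze_f)
      if (freeze_f) { J[1, 1] <- 1 }      # pin f
      dx <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(dx)) break
      if (freeze_f) dx[1] <- 0
      lam <- 1
      repeat {
        xn <- x + lam * dx
        if (all(xn >= 0) || lam < 1e-8) break
        lam <- lam / 2
      }
      if (any(xn < 0)) break
      x <- xn
      if (max(abs(homogeneous_rhs(x, params, freeze_f))) < 1e-11) { ok <- TRUE; break }
    }
    if (ok && all(is.finite(x))) {
      dup <- any(vapply(roots, function(r0)
        max(abs(r0 - x) / pmax(abs(x), 1e-8)) < 1e-4, TRUE))
      if (!dup) roots[[length(roots) + 1]] <- x
    }
  }
  if (length(roots) == 0) return(matrix(numeric(0), 0, 3,
                                        dimnames = list(NULL, c("f", "s", "p"))))
  out <- do.call(rbind, roots)
  colnames(out) <- c("f", "s", "p")
  out
}

#' Dispersion relation of the linearized model
#'
#' Largest real part of the eigenvalues of J - k^2 diag(D) over a wavenumber
#' grid, with the unstable band edges refined by bisection. The verdict
#' "Turing-positive" requires linear stability at k = 0 together with a
#' non-empty unstable band at k > 0 (diffusion-driven instability).
#'
#' @param params A [param_set()] (tissue diffusivities are used).
#' @param state Homogeneous steady state (f, s, p), e.g. a row of
#'   [uniform_steady_state()].
#' @param k Wavenumber grid (default: 400 log-spaced points in [1e-2, 1e2]).
#' @param freeze_f Analyze the frozen-FGF10 (two-species) subsystem.
#' @param bisect_tol Tolerance for the band-edge bisection.
#' @return Object of class \code{dispersion_result}: \code{k},
#'   \code{lambda_max}, \code{stable_at_zero}, band edges \code{k_lo},
#'   \code{k_hi} (NA if empty) and \code{turing}.
#' @export
dispersion <- function(params, state, k = NULL, freeze_f = FALSE,
                       bisect_tol = 1e-6) {
  if (is.null(k)) k <- 10^seq(-2, 2, length.out = 400)
  J <- reaction_jacobian(state, params, freeze_f)
  D <- diag(c(params$Df, params$Ds, params$Dp))
  if (freeze_f) { J <- J[2:3, 2:3]; D <- D[2:3, 2:3] }
  lmax <- function(kk)
    max(Re(eigen(J - kk^2 * D, only.values = TRUE)$values))
  lam <- vapply(k, lmax, 0)
  stable0 <- max(Re(eigen(J, only.values = TRUE)$values)) < 0
  k_lo <- k_hi <- NA_real_
  if (any(lam > 0)) {
    iu <- which(lam > 0)
    i1 <- iu[1]; i2 <- iu[length(iu)]
    k_lo <- if (i1 == 1) k[1] else
      stats::uniroot(lmax, c(k[i1 - 1], k[i1]), tol = bisect_tol)$root
    k_hi <- if (i2 == length(k)) k[length(k)] else
      stats::uniroot(lmax, c(k[i2], k[i2 + 1]), tol = bisect_tol)$root
  }
  structure(list(k = k, lambda_max = lam, stable_at_zero = stable0,
                 k_lo = k_lo, k_hi = k_hi,
                 turing = stable0 && !is.na(k_lo)),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  if (x$turing)
    cat(sprintf("Turing-positive: stable at k=0, unstable band [%.4g, %.4g], fastest wavelength %.3g\n",
                x$k_lo, x$k_hi, fastest_growing_wavelength(x)))
  else if (!x$stable_at_zero)
    cat("not Turing: homogeneous state unstable already at k = 0\n")
  else cat("not Turing: no unstable wavenumber band\n")
  invisible(x)
}

#' Wavelength of the fastest-growing mode
#'
#' @param disp A [dispersion()] result.
#' @return 2 pi / argmax_k Re lambda_max(k), or NA for an empty band.
#' @export
fastest_growing_wavelength <- function(disp) {
  if (is.na(disp$k_lo)) return(NA_real_)
  2 * pi / disp$k[which.max(disp$lambda_max)]
}

#' Closed-form dispersion of the classical Schnakenberg model
#'
#' For u_t = a - u + u^2 v + Du Lap u, v_t = b - u^2 v + Dv Lap v, the
#' homogeneous state is u* = a + b, v* = b/(a+b)^2 and the growth rate at
#' wavenumber k follows from the 2 x 2 eigenvalue problem in closed form.
#' Serves as the independent analytic oracle for [dispersion()].
#'
#' @param a,b Schnakenberg production parameters.
#' @param Du,Dv Diffusivities.
#' @param k Wavenumber grid.
#' @return List with \code{k}, \code{lambda_max}, \code{stable_at_zero},
#'   closed-form band edges \code{k_lo}, \code{k_hi} and \code{turing}.
#' @export
schnakenberg_dispersion <- function(a, b, Du, Dv, k) {
  u <- a + b
  fu <- (b - a) / (a + b)
  fv <- u^2
  gu <- -2 * b / (a + b)
  gv <- -u^2
  lam <- vapply(k, function(kk) {
    tr <- fu - Du * kk^2 + gv - Dv * kk^2
    de <- (fu - Du * kk^2) * (gv - Dv * kk^2) - fv * gu
    disc <- tr^2 - 4 * de
    if (disc >= 0) (tr + sqrt(disc)) / 2 else tr / 2
  }, 0)
  stable0 <- (fu + gv < 0) && (fu * gv - fv * gu > 0)
  # h(k^2) = Du Dv k^4 - (Dv fu + Du gv) k^2 + det J < 0 marks the band
  A <- Du * Dv; B <- Dv * fu + Du * gv; C <- fu * gv - fv * gu
  disc <- B^2 - 4 * A * C
  k_lo <- k_hi <- NA_real_
  if (B > 0 && disc > 0) {
    k2 <- c((B - sqrt(disc)) / (2 * A), (B + sqrt(disc)) / (2 * A))
    k_lo <- sqrt(k2[1]); k_hi <- sqrt(k2[2])
  }
  list(k = k, lambda_max = lam, stable_at_zero = stable0,
       k_lo = k_lo, k_hi = k_hi, turing = stable0 && !is.na(k_lo),
       u_star = u, v_star = b / (a + b)^2)
}

#' Turing certificate at a parameter point
#'
#' Finds the homogeneous steady state(s) and reports whether any is
#' diffusion-driven unstable (stable at k = 0, unstable band at k > 0).
#'
#' @param params A [param_set()].
#' @param ... Passed to [uniform_steady_state()].
#' @return List with \code{turing}, the steady \code{states}, and the
#'   [dispersion()] result of the first Turing-positive (or first) state.
#' @export
turing_verdict <- function(params, ...) {
  ss <- uniform_steady_state(params, ...)
  if (nrow(ss) == 0)
    return(list(turing = FALSE, states = ss, dispersion = NULL))
  best <- NULL
  for (i in seq_len(nrow(ss))) {
    d <- dispersion(params, ss[i, ])
    if (is.null(best)) best <- d
    if (d$turing) { best <- d; break }
  }
  list(turing = best$turing, states = ss, dispersion = best)
}
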
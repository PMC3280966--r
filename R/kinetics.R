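#' Hill repression factor
#'
#' Repression of FGF10 production by the SHH-Ptc complex:
#' \code{K^n / (K^n + c^n)}, monotone non-increasing in \code{c}, equal to 1
#' at \code{c = 0} and 1/2 at \code{c = K}.
#'
#' @param c Complex concentration (non-negative, vectorized).
#' @param K Hill constant (> 0).
#' @param n Hill coefficient (>= 1).
#' @return Repression factor in (0, 1].
#' @export
hill_repression <- function(c, K = 1, n = 2) {
  if (any(c < 0)) stop("negative concentration in hill_repression", call. = FALSE)
  stopifnot(K > 0, n >= 1)
  K^n / (K^n + c^n)
}

#' Hill activation factor
#'
#' Activation of SHH expression by FGF10: \code{f^n / (K^n + f^n)}, zero at
#' \code{f = 0}, 1/2 at \code{f = K}, saturating at 1.
#'
#' @param f FGF10 concentration (non-negative, vectorized).
#' @inheritParams hill_repression
#' @return Activation factor in [0, 1).
#' @export
hill_activation <- function(f, K = 1, n = 2) {
  if (any(f < 0)) stop("negative concentration in hill_activation", call. = FALSE)
  stopifnot(K > 0, n >= 1)
  f^n / (K^n + f^n)
}

#' Quasi-steady-state SHH-Ptc complex concentration
#'
#' When binding and unbinding are fast compared to the other kinetics the
#' bound-receptor concentration equilibrates to
#' \code{c = gamma * s^nS * p^mP} with effective binding constant
#' \code{gamma = kon / (koff + delta_c)}.
#'
#' @param s,p SHH and Ptc concentrations (non-negative, vectorized).
#' @param gamma Effective binding constant.
#' @param nS,mP Stoichiometry exponents (reference: one SHH, two Ptc).
#' @return Complex concentration.
#' @export
qssa_complex <- function(s, p, gamma = 1, nS = 1, mP = 2) {
  if (any(s < 0) || any(p < 0)) stop("negative concentration in qssa_complex",
                                     call. = FALSE)
  gamma * s^nS * p^mP
}

#' Reaction rates of the three-species QSSA model
#'
#' Returns the reaction part (production, decay and complex-mediated
#' consumption, no transport) of the f/s/p dynamics at the given subdomain:
#' FGF10 and Ptc production only in mesenchyme, SHH production only in
#' epithelium, decay wherever the species exists, and complex turnover
#' (rate \code{delta_c * c} of SHH, \code{mP * delta_c * c} of Ptc) in tissue
#' only. In the cavities Ptc is absent and its terms vanish.
#'
#' @param f,s,p Concentrations (vectorized, equal length).
#' @param params A [param_set()].
#' @param label Subdomain label: 1 lumen, 2 epithelium, 3 mesenchyme,
#'   4 interstitium/buffer (scalar or vector).
#' @return List with components \code{df}, \code{ds}, \code{dp}.
#' @export
reaction_rates <- function(f, s, p, params, label) {
  stopifnot(inherits(params, "lung_params"))
  if (!all(label %in% 1:4)) stop("unknown subdomain label", call. = FALSE)
  pr <- params
  tissue <- label %in% c(2, 3)
  mes <- label == 3
  epi <- label == 2
  cc <- ifelse(tissue, qssa_complex(s, p, pr$gamma, pr$nS, pr$mP), 0)
  df <- ifelse(mes, pr$nu_f * hill_repression(cc, pr$Kf, pr$n), 0) - pr$delta_f * f
  ds <- ifelse(epi, pr$nu_s * hill_activation(f, pr$Ks, pr$n), 0) -
    pr$delta_s * s - ifelse(tissue, pr$delta_c * cc, 0)
  dp <- ifelse(mes, pr$rho0 + pr$rho1 * cc, 0) -
    ifelse(tissue, pr$delta_p, 0) * p - ifelse(tissue, pr$mP * pr$delta_c * cc, 0)
  list(df = df, ds = ds, dp = dp)
}
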
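test_that("Hill functions hit their anchor values and are monotone", {
  expect_equal(hill_repression(0, K = 2, n = 2), 1)
  expect_equal(hill_repression(2, K = 2, n = 2), 0.5)
  expect_equal(hill_repression(20, K = 2, n = 2), 1 / 101)
  expect_equal(hill_activation(0, K = 3, n = 2), 0)
  expect_equal(hill_activation(3, K = 3, n = 2), 0.5)
  expect_equal(hill_activation(1e9, K = 3, n = 2), 1, tolerance = 1e-8)
  cc <- seq(0, 10, by = 0.1)
  expect_true(all(diff(hill_repression(cc, 1, 2)) <= 0))
  expect_true(all(diff(hill_activation(cc, 1, 2)) >= 0))
  expect_error(hill_repression(-1), "negative")
  expect_error(hill_activation(-1), "negative")
})

test_that("QSSA complex equals the equilibrium of the explicit binding ODE", {
  expect_equal(qssa_complex(0, 3), 0)
  expect_equal(qssa_complex(1, 1, gamma = 1), 1)
  skip_if_not_installed("deSolve")
  # oracle: integrate dc/dt = kon s p^mP - (koff + delta_c) c to equilibrium
  kon <- 1.7; koff <- 0.8; delta_c <- 1.0
  s <- 0.6; p <- 1.4
  out <- deSolve::ode(c(c = 0), seq(0, 60, by = 0.5),
                      function(t, y, parms) list(kon * s * p^2 - (koff + delta_c) * y),
                      parms = NULL)
  c_eq <- out[nrow(out), "c"]
  gamma <- kon / (koff + delta_c)
  expect_equal(unname(c_eq), qssa_complex(s, p, gamma), tolerance = 1e-6)
})

test_that("reaction rates are compartment-gated", {
  p <- reference_params()
  # lumen: no production anywhere, all concentrations zero -> exactly zero
  r <- reaction_rates(0, 0, 0, p, label = 1)
  expect_equal(unlist(r), c(df = 0, ds = 0, dp = 0))
  # epithelium at FGF10 half-saturation: SHH production at half its maximum
  r <- reaction_rates(p$Ks, 0, 0, p, label = 2)
  expect_equal(r$ds, p$nu_s / 2)
  # buffer: only decay acts on f and s
  r <- reaction_rates(2, 3, 0, p, label = 4)
  expect_equal(r$df, -p$delta_f * 2)
  expect_equal(r$ds, -p$delta_s * 3)
  expect_error(reaction_rates(0, 0, 0, p, label = 7), "label")
})

test_that("frozen-FGF10 kinetics equal an independently coded Schnakenberg RHS", {
  p <- reference_params()
  p$delta_s <- 0                       # the limit neglects SHH decay
  f0 <- 0.7
  sl <- schnakenberg_limit(p, f_const = f0)
  # independent Schnakenberg right-hand side (textbook form)
  schnak <- function(u, v, a, b) c(du = a - u + u^2 * v, dv = b - u^2 * v)
  set.seed(4)
  for (i in 1:12) {
    s <- runif(1, 0, 3); pp <- runif(1, 0, 3)
    r3 <- homogeneous_rhs(c(f0, s, pp), p, freeze_f = TRUE)
    u <- sl$beta * pp; v <- sl$alpha * s
    r2 <- schnak(u, v, sl$a, sl$b)
    # map back: time rescaled by delta_p, variables by beta/alpha
    expect_equal(r3[3], r2[["du"]] * sl$time_scale / sl$beta, tolerance = 1e-12)
    expect_equal(r3[2], r2[["dv"]] * sl$time_scale / sl$alpha, tolerance = 1e-12)
  }
})

test_that("schnakenberg_limit maps anchor cases and validates", {
  p <- reference_params()
  p0 <- p; p0$rho0 <- 0
  expect_equal(schnakenberg_limit(p0, 1)$a, 0)
  expect_true(length(schnakenberg_limit(p, 1)$warnings) == 0)  # delta_s small here
  pbad <- p; pbad$rho1 <- 0.1
  expect_error(schnakenberg_limit(pbad, 1), "autocatalysis")
})

test_that("redimensionalization reproduces the dimensional table", {
  sc <- lung_scales(L_um = 50, T_s = 1000)
  tab <- redimensionalize(reference_params(), sc)
  get <- function(nm) tab$dimensional[tab$parameter == nm]
  expect_equal(get("Dp"), 0.05)          # um^2/s, receptor
  expect_equal(get("Df"), 2.5)           # FGF10 in tissue
  expect_equal(get("Ds"), 12.5)          # SHH in tissue
  expect_equal(get("D_cavity"), 100)     # cavities
  # identity scales return the dimensionless values unchanged
  tid <- redimensionalize(reference_params(), lung_scales(1, 1))
  expect_equal(tid$dimensional, tid$dimensionless)
  expect_equal(speed_to_um_per_h(14 / 180, sc), 14)
})

test_that("parameter validation rejects bad sets and scale_params works", {
  expect_error(param_set(Df = -1), "non-negative")
  expect_error(param_set(Df = 50, D_cavity = 40), "cavity diffusivity")
  expect_warning(param_set(nS = 1L, mP = 1L), "Turing")
  p <- scale_params(reference_params(), c(nu_f = 0.75))
  expect_equal(p$nu_f, 0.75 * reference_params()$nu_f)
  expect_error(scale_params(reference_params(), c(zeta = 2)), "unknown parameter")
})
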
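tiny <- function() make_fixture("tiny_mesh")$mesh

test_that("zero production keeps the zero state exactly", {
  p <- scale_params(reference_params(), c(nu_f = 0, nu_s = 0, rho0 = 0, rho1 = 0))
  traj <- integrate_rd(tiny(), p, t_end = 5, perturb_amplitude = 0)
  expect_true(all(vapply(traj$frames, function(fr) all(fr == 0), TRUE)))
})

test_that("decay-only dynamics follow the exponential closed form", {
  m <- tiny()
  delta <- c(0.5, 1.2, 0.8)
  p <- param_set(nu_f = 0, nu_s = 0, rho0 = 0, rho1 = 0,
                 delta_f = delta[1], delta_s = delta[2], delta_p = delta[3],
                 delta_c = 0)
  nc <- m$Nx * m$Ny
  init <- cbind(rep(2, nc), rep(3, nc), rep(1, nc))
  init[as.vector(m$labels) %in% c(1, 4), 3] <- 0     # Ptc lives in tissue only
  traj <- integrate_rd(m, p, t_end = 4, dt = 0.005,
                       bc = boundary_condition("no_flux"),
                       init = init, perturb_amplitude = 0)
  i <- length(traj$times)
  t <- traj$times[i]
  tissue <- as.vector(traj$labels) %in% c(2, 3)
  for (q in 1:3) {
    expected <- init[tissue, q][1] * exp(-delta[q] * t)
    # backward Euler under-decays by about t * delta^2 * dt / 2
    expect_equal(mean(traj$frames[[i]][tissue, q]), expected, tolerance = 0.02)
  }
})

test_that("identical configuration and seed give bit-identical trajectories", {
  m <- tiny()
  p <- reference_params()
  a <- integrate_rd(m, p, t_end = 3, seed = 42)
  b <- integrate_rd(m, p, t_end = 3, seed = 42)
  expect_identical(a$frames, b$frames)
  d <- integrate_rd(m, p, t_end = 3, seed = 43)
  expect_false(identical(a$frames[[length(a$frames)]],
                         d$frames[[length(d$frames)]]))
})

test_that("fields stay non-negative from non-negative initial data", {
  set.seed(21)
  m <- tiny()
  for (i in 1:4) {
    p <- scale_params(reference_params(),
                      stats::setNames(runif(2, 0.5, 2), c("nu_s", "delta_c")))
    traj <- integrate_rd(m, p, t_end = 5, seed = i)
    expect_true(all(traj$frames[[length(traj$frames)]] >= 0))
  }
})

test_that("steady flag is consistent with the residual tolerance", {
  rep <- ref_steady()
  expect_true(rep$steady)
  expect_lt(tail(rep$resid, 1), 1e-6)
  # a run stopped early cannot claim steadiness
  m <- tiny()
  short <- run_to_steady(m, reference_params(), t_max = 3, tol = 1e-12,
                         steady_min_t = 1)
  expect_false(short$steady)
})

test_that("the explicit-complex kinetics match an independent ODE integration", {
  skip_if_not_installed("deSolve")
  m <- tiny()
  # uniform tissue fields with production off and sealed boundaries reduce
  # the PDE to the pointwise binding/turnover ODE system
  p <- param_set(nu_f = 0, nu_s = 0, rho0 = 0, rho1 = 0,
                 delta_f = 0.3, delta_s = 0.2, delta_p = 0.4, delta_c = 1,
                 kon = 1.5, koff = 0.7)
  nc <- m$Nx * m$Ny
  tissue <- as.vector(m$labels) %in% c(2, 3)
  init <- cbind(rep(1, nc), rep(2, nc), tissue * 1.5, 0)
  traj <- integrate_rd(m, p, t_end = 3, dt = 0.01, model = "full",
                       bc = boundary_condition("no_flux"),
                       init = init, perturb_amplitude = 0)
  fr <- traj$frames[[length(traj$frames)]]
  ode <- deSolve::ode(c(f = 1, s = 2, pp = 1.5, cc = 0),
                      seq(0, 3, 0.05),
                      function(t, y, pm) with(as.list(y), {
                        bind <- 1.5 * s * pp^2 - 0.7 * cc   # net complex formation
                        list(c(-0.3 * f, -0.2 * s - bind,
                               -0.4 * pp - 2 * bind, bind - 1 * cc))
                      }), NULL)
  expected <- ode[nrow(ode), c("f", "s", "pp", "cc")]
  got <- colMeans(fr[tissue, ])
  expect_equal(unname(got), unname(expected), tolerance = 0.02)
  expect_true(all(fr >= 0))
  expect_equal(ncol(fr), 4)
  expect_error(integrate_rd(m, reference_params(), t_end = 1, model = "full"),
               "kon")
})

test_that("input validation catches malformed calls", {
  m <- tiny()
  expect_error(integrate_rd(m, reference_params(), t_end = 0), "t_end")
  expect_error(integrate_rd(m, reference_params(), t_end = 1,
                            init = matrix(0, 5, 3)), "cells")
})

test_that("open far-field solution is insensitive to the buffer width", {
  # smooth unique steady state (no Turing multistability): mP = nS = 1
  psm <- suppressWarnings(param_set(mP = 1L, nS = 1L))
  run_at <- function(Lfar) {
    m <- make_mesh(lung_geometry(Lfar = Lfar), hmax = 0.2)
    r <- run_to_steady(m, psm, t_max = 120, tol = 1e-7, steady_min_t = 10)
    list(m = m, s = r$state)
  }
  a <- run_at(4); b <- run_at(8)
  ca <- mesh_cells(a$m); cb <- mesh_cells(b$m)
  ta <- ca$label %in% 2:3; tb <- cb$label %in% 2:3
  i <- match(paste(round(ca$x[ta], 3), round(ca$y[ta], 3)),
             paste(round(cb$x[tb], 3), round(cb$y[tb], 3)))
  for (q in 1:3) {
    rel <- max(abs(a$s[ta, q] - b$s[tb, q][i]), na.rm = TRUE) / max(a$s[ta, q])
    expect_lt(rel, 0.01)
  }
  # the patterned reference keeps its class and spot count when doubling Lfar
  m4 <- make_mesh(lung_geometry(Lfar = 4), hmax = 0.2)
  r4 <- run_to_steady(m4, reference_params(), t_max = 300, tol = 1e-6)
  pr4 <- pattern_report(r4$trajectory)
  pr2 <- pattern_report(ref_steady()$trajectory)
  expect_equal(pr4$class, pr2$class)
})
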
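test_that("uniform growth height follows the exponential closed form", {
  expect_equal(uniform_growth_height(2, 0, 10), 2)
  expect_equal(uniform_growth_height(2, 0.1, log(2) / 0.1), 4)
  skip_if_not_installed("deSolve")
  out <- deSolve::ode(c(h = 1.5), seq(0, 20, 1),
                      function(t, y, p) list(0.05 * y), NULL)
  expect_equal(unname(out[, "h"]), uniform_growth_height(1.5, 0.05, out[, "time"]),
               tolerance = 1e-6)
})

test_that("growth specifications validate their inputs", {
  expect_error(growth_spec("uniform"), "mu")
  expect_error(growth_spec("graded", v = 0.1), "ratio")
  expect_error(growth_spec("graded", v = 0.1, ratio = 0.5), "ratio")
  expect_error(growth_spec("tip", v = -1), "speed")
  expect_s3_class(growth_spec("tip", v = 0.1), "growth_spec")
})

test_that("pure growth conserves mass for every mode (reactions off, closed)", {
  p_off <- param_set(nu_f = 0, nu_s = 0, rho0 = 0, rho1 = 0,
                     delta_f = 0, delta_s = 0, delta_p = 0, delta_c = 0)
  mesh <- make_mesh(lung_geometry(), hmax = 0.25, final_height = 10)
  nc <- mesh$Nx * mesh$Ny
  set.seed(3)
  init <- cbind(runif(nc), runif(nc), runif(nc))
  for (gr in list(growth_spec("tip", v = 0.1),
                  growth_spec("uniform", mu = 0.02),
                  growth_spec("graded", v = 0.1, ratio = 3))) {
    traj <- grow_and_solve(mesh, p_off, gr, t_end = 30,
                           bc = boundary_condition("no_flux"),
                           init = init, perturb_amplitude = 0)
    tm <- total_mass(traj)
    for (sp in c("f", "s", "p")) {
      drift <- (max(tm[[sp]]) - min(tm[[sp]])) / tm[[sp]][1]
      expect_lt(drift, 0.005)
    }
    expect_true(all(diff(traj$L) >= 0))        # h(t) monotone
  }
})

test_that("dilution under uniform stretching never increases concentrations", {
  p_off <- param_set(nu_f = 0, nu_s = 0, rho0 = 0, rho1 = 0,
                     delta_f = 0, delta_s = 0, delta_p = 0, delta_c = 0)
  mesh <- make_mesh(lung_geometry(), hmax = 0.25, final_height = 9)
  nc <- mesh$Nx * mesh$Ny
  init <- cbind(rep(1, nc), rep(1, nc), rep(0, nc))
  traj <- grow_and_solve(mesh, p_off, growth_spec("uniform", mu = 0.03),
                         t_end = 20, init = init, perturb_amplitude = 0)
  tots <- sapply(traj$frames, function(fr) max(fr[, 1]))
  expect_true(all(diff(tots) <= 1e-9))
})

test_that("zero growth speed reproduces the fixed-domain trajectory", {
  mesh <- make_mesh(lung_geometry(), hmax = 0.25)
  p <- reference_params()
  static <- integrate_rd(mesh, p, t_end = 5)
  moving <- grow_and_solve(mesh, p, growth_spec("tip", v = 0), t_end = 5)
  i <- length(static$frames)
  expect_equal(static$frames[[i]], moving$frames[[i]], tolerance = 1e-10)
})

test_that("branch events: a settled fixed-domain run has no events", {
  traj <- ref_steady()$trajectory
  # once the run is steady the recorded frames are identical, so no new
  # spot position may register as an event
  ev <- branch_events(traj, t_min = max(traj$times) - 25)
  expect_equal(nrow(ev), 0)
})

test_that("tip growth seeds new maxima behind the advancing tip", {
  traj <- fast_growth()
  ev <- branch_events(traj, t_min = 30)
  expect_gt(nrow(ev), 0)
  bl <- branch_site_location_mode(traj$growth, traj, t_min = 30)
  expect_equal(bl$mode, "behind_tip")
  # every event sits below the instantaneous stalk top plus the cap
  expect_true(all(ev$y <= ev$tip_y + 4))
})
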
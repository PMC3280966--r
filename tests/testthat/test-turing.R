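test_that("Schnakenberg homogeneous state and Turing verdict match closed forms", {
  fx <- make_fixture("schnakenberg_point")
  k <- 10^seq(-2, 1.5, length.out = 200)
  d <- schnakenberg_dispersion(fx$a, fx$b, fx$Du, fx$Dv, k)
  expect_equal(d$u_star, fx$a + fx$b)
  expect_equal(d$v_star, fx$b / (fx$a + fx$b)^2)
  expect_true(d$turing)
  # equal diffusivities with stable kinetics: lambda(k) = lambda(0) - D k^2 < 0
  d_eq <- schnakenberg_dispersion(fx$a, fx$b, fx$Dv, fx$Dv, k)
  expect_true(d_eq$stable_at_zero)
  expect_false(d_eq$turing)
  expect_true(all(d_eq$lambda_max < 0))
})

test_that("three-species dispersion with frozen FGF10 matches the analytic oracle", {
  p <- reference_params()
  p$delta_s <- 0
  f0 <- 1
  ss <- uniform_steady_state(p, freeze_f = TRUE, f_const = f0, n_start = 30)
  expect_gt(nrow(ss), 0)
  sl <- schnakenberg_limit(p, f_const = f0)
  # closed-form check of the steady state through the variable mapping
  expect_equal(unname(ss[1, "p"]) * sl$beta, sl$a + sl$b, tolerance = 1e-7)
  k <- 10^seq(-2, 2, length.out = 300)
  d3 <- dispersion(p, ss[1, ], k = k, freeze_f = TRUE)
  d2 <- schnakenberg_dispersion(sl$a, sl$b, sl$Du, sl$Dv, k)
  expect_lt(max(abs(d3$lambda_max - sl$time_scale * d2$lambda_max)), 1e-8)
})

test_that("fastest-growing wavelength equals a brute-force argmax", {
  fx <- make_fixture("schnakenberg_point")
  kf <- 10^seq(-2, 1.5, length.out = 4000)     # independent fine grid
  lam <- schnakenberg_dispersion(fx$a, fx$b, fx$Du, fx$Dv, kf)$lambda_max
  k_star_bruteforce <- kf[which.max(lam)]
  p <- reference_params()
  ss <- uniform_steady_state(p, n_start = 30)
  d <- dispersion(p, ss[1, ])
  expect_equal(fastest_growing_wavelength(d), 2 * pi / d$k[which.max(d$lambda_max)])
  d2 <- schnakenberg_dispersion(fx$a, fx$b, fx$Du, fx$Dv,
                                10^seq(-2, 1.5, length.out = 400))
  expect_equal(2 * pi / d2$k[which.max(d2$lambda_max)], 2 * pi / k_star_bruteforce,
               tolerance = 0.02)
})

test_that("uniform steady state solves the kinetics and handles trivial cases", {
  p0 <- reference_params()
  pz <- scale_params(p0, c(nu_f = 0, nu_s = 0, rho0 = 0, rho1 = 0))
  ss <- uniform_steady_state(pz, n_start = 20)
  expect_true(any(rowSums(abs(ss)) < 1e-8))    # origin is the fixed point
  ss0 <- uniform_steady_state(p0, n_start = 40)
  expect_gt(nrow(ss0), 0)
  expect_true(all(ss0 >= 0))
  for (i in seq_len(nrow(ss0)))
    expect_lt(max(abs(homogeneous_rhs(ss0[i, ], p0))), 1e-9)
})

test_that("reaction Jacobian matches central finite differences", {
  p <- reference_params()
  set.seed(9)
  for (i in 1:8) {
    x <- runif(3, 0.1, 3)
    J <- reaction_jacobian(x, p)
    eps <- 1e-6
    Jfd <- sapply(1:3, function(j) {
      e <- numeric(3); e[j] <- eps
      (homogeneous_rhs(x + e, p) - homogeneous_rhs(x - e, p)) / (2 * eps)
    })
    expect_equal(J, Jfd, tolerance = 1e-5)
  }
})

test_that("stoichiometry mP = nS = 1 admits no diffusion-driven instability", {
  for (fac in c(0.5, 1, 2)) {
    p1 <- suppressWarnings(scale_params(param_set(mP = 1L, nS = 1L),
                                        c(nu_s = fac)))
    tv <- suppressWarnings(turing_verdict(p1, n_start = 30))
    expect_false(tv$turing)
  }
})
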
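test_that("spot detection recovers constructed Gaussian bumps exactly", {
  fx <- make_fixture("gaussian_spots_field", seed = 1, n_spots = 3)
  sp <- detect_spots(fx$field, fx$mesh)
  expect_equal(nrow(sp), 3)
  found <- sp[order(-sp$y), ]
  expect_true(all(abs(found$x - fx$centers$x) <= fx$mesh$hmax))
  expect_true(all(abs(found$y - fx$centers$y) <= fx$mesh$hmax))
})

test_that("sub-threshold bumps and empty fields yield no spots", {
  fx <- make_fixture("gaussian_spots_field", seed = 2, n_spots = 2)
  # add a dominant bump so the others fall below the relative threshold
  cells <- mesh_cells(fx$mesh)
  big <- 10 * exp(-((cells$x - fx$centers$x[1])^2 +
                    (cells$y - fx$centers$y[1])^2) / (2 * 0.15^2))
  f2 <- fx$field + matrix(big, fx$mesh$Nx, fx$mesh$Ny)
  sp <- detect_spots(f2, fx$mesh, theta_rel = 0.5)
  expect_equal(nrow(sp), 1)
  expect_equal(nrow(detect_spots(matrix(0, fx$mesh$Nx, fx$mesh$Ny), fx$mesh)), 0)
  expect_error(detect_spots(fx$field, fx$mesh, theta_rel = 1.2), "theta_rel")
})

test_that("classification covers the four modes from constructed spot tables", {
  tip <- data.frame(x = 0, y = 3.4, value = 1, zone = "tip")
  fl <- data.frame(x = c(-1.5, 1.5), y = c(1, 1), value = 0.8, zone = "flank")
  sh <- data.frame(x = c(-1.3, 1.3), y = c(2.8, 2.8), value = 0.9,
                   zone = "shoulder")
  none <- tip[0, ]
  expect_equal(classify_mode(tip), "elongation")
  expect_equal(classify_mode(rbind(tip, fl)), "lateral")
  expect_equal(classify_mode(sh), "bifurcation")
  expect_equal(classify_mode(none), "none")
})

test_that("classification is invariant to uniform rescaling of the field", {
  rep <- ref_steady()
  f <- field_matrix(rep$trajectory, "f")
  m <- rep$trajectory$mesh
  for (th in c(0.2, 0.3, 0.4)) {
    a <- detect_spots(f, m, theta_rel = th)
    b <- detect_spots(f * 1000, m, theta_rel = th)
    expect_equal(a[c("x", "y", "zone")], b[c("x", "y", "zone")])
  }
})

test_that("axial spacing clusters mirror pairs and reports gaps", {
  sp <- data.frame(x = c(-1, 1, -1, 1, 0), y = c(0, 0, 1.5, 1.5, 3),
                   value = 1, zone = "flank")
  a <- axial_spacing(sp)
  expect_equal(a$positions, c(0, 1.5, 3))
  expect_equal(a$gaps, c(1.5, 1.5))
  expect_equal(a$mean, 1.5)
  expect_null(axial_spacing(sp[1, ]))
  expect_null(axial_spacing(sp[1:2, ]))       # one ring only
})

test_that("detection is stable under mesh refinement", {
  p0 <- reference_params()
  pr2 <- pattern_report(ref_steady()$trajectory)
  m1 <- make_mesh(lung_geometry(), hmax = 0.1)
  r1 <- run_to_steady(m1, p0, t_max = 300, tol = 1e-6)
  pr1 <- pattern_report(r1$trajectory)
  expect_equal(pr1$class, pr2$class)
  expect_equal(nrow(pr1$spots), nrow(pr2$spots))
})

test_that("the fast-growth profile is a regular sequence of branch rings", {
  traj <- fast_growth()
  pr <- pattern_report(traj)
  expect_equal(pr$class, "lateral")
  nontip <- pr$spots[pr$spots$zone != "tip", ]
  expect_gt(nrow(nontip), 3)
  # rings are near-periodic along the stalk and of comparable intensity
  sp <- axial_spacing(pr$spots)
  expect_lt(stats::sd(sp$gaps) / mean(sp$gaps), 0.5)
  expect_lt(max(nontip$value) / min(nontip$value), 1.5)
})
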
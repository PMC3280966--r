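test_that("subdomain areas match the closed-form geometry", {
  g <- lung_geometry()
  # independent oracle: stalk rectangles plus half-annuli over the cap
  h <- g$h0
  re <- g$rc + g$we
  lumen <- 2 * g$rc * h + pi / 2 * g$rc^2
  epi <- 2 * g$we * h + pi / 2 * (re^2 - g$rc^2)
  mes <- 2 * (g$Rc - re) * h + pi / 2 * (g$Rc^2 - re^2)
  expect_equal(unname(geometry_areas(g)), c(lumen, epi, mes))
  expect_gt(geometry_areas(g)[["epithelium"]], 0)
})

test_that("invalid geometries are rejected with the violated inequality", {
  expect_error(lung_geometry(we = 0), "degenerate epithelium")
  expect_error(lung_geometry(rc = 1.9, we = 0.2, Rc = 2), "rc \\+ we < Rc")
  expect_error(lung_geometry(Lfar = 0), "Lfar")
  expect_error(lung_geometry(stalk_truncation_fraction = 1), "truncation")
})

test_that("deformations follow the tip/stalk protocols and compose", {
  g <- lung_geometry()
  d <- apply_deformation(g, tip_epithelium_scale = 1.25)
  expect_equal(d$tip_epithelium_scale, 1.25)
  expect_equal(effective_stalk <- d$h0, g$h0)   # stalk unchanged
  tr <- apply_deformation(g, stalk_truncation_fraction = 0.8)
  expect_equal(tr$h0 * (1 - tr$stalk_truncation_fraction), 0.2 * g$h0)
  id <- apply_deformation(g)
  expect_identical(unclass(id), unclass(g))     # identity, field-for-field
  expect_error(apply_deformation(g, tip_epithelium_scale = 2),
               "rc \\+ we < Rc")
})

test_that("any valid deformation of a valid geometry is valid (closure)", {
  set.seed(11)
  for (i in 1:25) {
    d <- apply_deformation(lung_geometry(),
                           tip_epithelium_scale = runif(1, 0.8, 1.3),
                           tip_mesenchyme_scale = runif(1, 0.95, 1.2),
                           stalk_truncation_fraction = runif(1, 0, 0.9))
    expect_s3_class(d, "lung_geometry")
  }
})

test_that("mesh labels partition the bounding box and refine consistently", {
  g <- lung_geometry()
  counts <- sapply(c(0.4, 0.2, 0.1, 0.05), function(h) {
    m <- make_mesh(g, hmax = h)
    expect_true(all(m$labels %in% 1:4))
    a <- mesh_areas(m)
    half_w <- g$Rc + g$Lfar
    expect_equal(sum(a), 2 * half_w * m$L0, tolerance = 1e-10)
    m$Nx * m$Ny
  })
  expect_true(all(diff(counts) > 0))            # node count grows as hmax falls
  # meshed tissue areas approach the analytic ones at O(hmax)
  for (h in c(0.2, 0.1)) {
    m <- make_mesh(g, hmax = h)
    a <- mesh_areas(m)[1:3]
    exact <- geometry_areas(g)
    # interface-cell misclassification is bounded by perimeter * hmax
    expect_lt(max(abs(a - exact)), 12 * h)
  }
  err <- sapply(c(0.2, 0.05), function(h)
    max(abs(mesh_areas(make_mesh(g, hmax = h))[1:3] - geometry_areas(g))))
  expect_lt(err[2], err[1])
})

test_that("hmax must be positive and labels respect deformations", {
  expect_error(make_mesh(lung_geometry(), hmax = 0), "hmax")
  g <- apply_deformation(lung_geometry(), tip_mesenchyme_scale = 1.1)
  m0 <- make_mesh(lung_geometry(), hmax = 0.2)
  m1 <- make_mesh(g, hmax = 0.2)
  expect_gt(sum(m1$labels == 3) * m1$hx * m1$L0 / m1$Ny,
            sum(m0$labels == 3) * m0$hx * m0$L0 / m0$Ny)
})

test_that("VTK round trip preserves mesh labels and fields", {
  m <- make_mesh(lung_geometry(), hmax = 0.4)
  f <- list(f = matrix(runif(m$Nx * m$Ny), m$Nx, m$Ny))
  path <- tempfile(fileext = ".vtk")
  write_field_vtk(m, path, fields = f)
  back <- read_field_vtk(path)
  expect_equal(back$label, unname(m$labels))
  expect_equal(back$f, f$f, tolerance = 1e-8)
  expect_equal(back$x, m$x, tolerance = 1e-8)
})
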
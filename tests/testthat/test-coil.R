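test_that("polygonal Biot-Savart converges to the on-axis closed form", {
  a <- 0.045  # 45 mm in metres
  mu0 <- 4 * pi * 1e-7
  gamma <- 42.5775e6
  zs <- c(0, 10, 25, 60, 120)  # mm along the loop axis
  closed <- gamma * mu0 * a^2 / (2 * (a^2 + (zs * 1e-3)^2)^1.5)
  loop <- loop_geometry(c(0, 0, 0), 45, normal = c(0, 0, 1), n_segments = 256)
  # evaluate at each on-axis point via a 1-voxel grid
  for (i in seq_along(zs)) {
    g1 <- grid3d(c(1, 1, 1), c(1, 1, 1), origin_mm = c(0, 0, zs[i]))
    got <- loop_profile(loop, g1)$values[1, 1, 1]
    expect_equal(got, closed[i], tolerance = 1e-3)  # 0.1 %
  }
  # far-field decay is monotone on axis
  vals <- vapply(seq(50, 250, by = 50), function(z)
    loop_profile(loop, grid3d(c(1, 1, 1), c(1, 1, 1),
                              origin_mm = c(0, 0, z)))$values[1], numeric(1))
  expect_true(all(diff(vals) < 0) && all(vals > 0))
})

test_that("reversing the loop normal negates the profile", {
  g <- grid3d(c(6, 6, 4), c(4, 4, 5))
  up <- loop_profile(loop_geometry(c(10, -20, 10), 30, c(0, 1, 0)), g)
  dn <- loop_profile(loop_geometry(c(10, -20, 10), 30, c(0, -1, 0)), g)
  expect_equal(up$values, -dn$values, tolerance = 1e-12)
})

test_that("voxels on the wire are flagged invalid", {
  g <- grid3d(c(3, 1, 1), c(30, 1, 1), origin_mm = c(0, 0, 0))
  # loop of radius 30 mm centred at x = 30: the voxel at x = 60 sits close
  # to the wire only if on the circle; place one voxel exactly on it
  loop <- loop_geometry(c(30, 0, 0), 30, normal = c(0, 0, 1))
  prof <- loop_profile(loop, g)
  expect_true(is.na(prof$values[3, 1, 1]))   # (60, 0, 0) lies on the circle
  expect_false(is.na(prof$values[2, 1, 1]))  # loop centre is fine
})

test_that("array profiles stack loops; duplicates are tolerated, dup names not", {
  g <- small_grid()
  l1 <- loop_geometry(c(24, -30, 10), 30, c(0, 1, 0))
  one <- array_profiles(list(l1), g)
  expect_equal(one$n_channels, 1L)
  expect_equal(one$profiles[, , , 1], loop_profile(l1, g)$values)
  two <- array_profiles(list(l1, l1), g)
  expect_equal(two$profiles[, , , 1], two$profiles[, , , 2])
  expect_error(array_profiles(list(l1, l1), g, names = c("a", "a")),
               "duplicate")
  expect_equal(length(default_loop_layout(g)), 15L)
  co15 <- array_profiles(default_loop_layout(grid3d(c(8, 8, 7), c(8, 8, 5))),
                         grid3d(c(8, 8, 7), c(8, 8, 5)))
  expect_equal(co15$n_channels, 15L)
})

test_that("rank-deficient (duplicated) channels do not break the optimizer", {
  g <- small_grid()
  l1 <- loop_geometry(c(24, -30, 10), 30, c(0, 1, 0))
  co <- array_profiles(list(l1, l1), g)
  base <- field_map(-2 * co$profiles[, , , 1], g)
  m <- full_mask(g)
  I <- optimize_slice(base, co, m, 4, shim_control(w = 0, ridge = 1e-9))
  expect_equal(attr(I, "status"), "ok")
  # minimum-norm tie-break shares the current between the twins
  # (up to the QP's ~1e-4 A accuracy on this rank-deficient problem)
  expect_equal(I[[1]], I[[2]], tolerance = 1e-3)
  expect_equal(sum(I), 2, tolerance = 1e-3)
})

test_that("spherical-harmonic basis has the documented structure", {
  g <- grid3d(c(7, 7, 7), c(4, 4, 5))
  expect_equal(sh_basis(g, 0)$n_channels, 1L)
  expect_true(all(sh_basis(g, 0)$profiles == sh_basis(g, 0)$profiles[1, 1, 1, 1]))
  sh1 <- sh_basis(g, 1)
  expect_equal(sh1$n_channels, 4L)
  zch <- sh1$profiles[, , , match("z", sh1$names)]
  fz <- field_map(zch, g)
  grads <- vapply(2:6, function(s)
    through_slice_gradient(fz, s)[3, 5], numeric(1))
  expect_equal(max(abs(grads - grads[1])), 0, tolerance = 1e-12)
  sh2 <- sh_basis(g, 2)
  expect_equal(sh2$n_channels, 9L)
  A <- matrix(sh2$profiles, ncol = 9)
  expect_equal(qr(crossprod(A))$rank, 9L)  # Gram matrix full rank
  # unit RMS normalization
  expect_equal(sqrt(colMeans(A^2)), rep(1, 9), tolerance = 1e-12)
})

test_that("combine_field is affine in the currents", {
  g <- small_grid()
  fx <- small_coil3()
  base <- random_smooth_field(g, 55)
  expect_equal(combine_field(base, fx$coil, c(0, 0, 0))$values, base$values)
  set.seed(56)
  I1 <- rnorm(3); I2 <- rnorm(3)
  lhs <- combine_field(base, fx$coil, I1 + I2)$values
  rhs <- combine_field(combine_field(base, fx$coil, I1), fx$coil, I2)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
  zero <- field_map(array(0, g$shape), g)
  diff <- combine_field(base, fx$coil, I1 + I2)$values -
    combine_field(base, fx$coil, I1)$values
  expect_equal(diff, combine_field(zero, fx$coil, I2)$values,
               tolerance = 1e-10)
  # single-channel exact cancellation
  one <- coil_profiles(fx$coil$profiles[, , , 1, drop = FALSE], g)
  b1 <- field_map(one$profiles[, , , 1], g)
  expect_equal(max(abs(combine_field(b1, one, -1)$values)), 0,
               tolerance = 1e-12)
  expect_error(combine_field(base, fx$coil, c(1, 2)), "per channel")
})
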
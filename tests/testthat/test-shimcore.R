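test_that("through-slice gradient is exact on constants, lines, quadratics", {
  g <- grid3d(c(4, 4, 7), c(2, 2, 5))
  expect_equal(max(abs(through_slice_gradient(uniform_field(g, 42), 4))), 0)
  gr <- through_slice_gradient(ramp_field(g, 3), 4)
  expect_equal(max(abs(gr - 3)), 0, tolerance = 1e-12)
  expect_false(attr(gr, "onesided"))
  # quadratic: central difference at the slice centre is exact (f = z^2)
  z <- axis_coords(g, 3)
  quad <- field_map(array(rep(z^2, each = 16), g$shape), g)
  g10 <- through_slice_gradient(quad, 3, 5)  # slice 3 sits at z = 10
  expect_equal(unname(g10[1, 1]), (12.5^2 - 7.5^2) / 5, tolerance = 1e-12)
  expect_equal(unname(g10[1, 1]), 20)
})

test_that("volume ends fall back to a flagged one-sided difference", {
  g <- grid3d(c(3, 3, 4), c(2, 2, 5))
  f <- ramp_field(g, 2)
  lo <- through_slice_gradient(f, 1)
  hi <- through_slice_gradient(f, 4)
  expect_true(attr(lo, "onesided") && attr(hi, "onesided"))
  expect_equal(max(abs(lo - 2)), 0, tolerance = 1e-12)  # exact on a line
  g1 <- grid3d(c(3, 3, 1), c(2, 2, 5))
  expect_error(through_slice_gradient(uniform_field(g1), 1), "planes")
})

test_that("slice objective follows the documented convention", {
  # 2 masked voxels, field (3, 4) Hz, gradient (1, 1) Hz/mm on the slice
  g <- grid3d(c(2, 1, 3), c(1, 1, 5))
  z <- axis_coords(g, 3)
  vals <- array(0, g$shape)
  vals[1, 1, ] <- 3 + 1 * (z - z[2])
  vals[2, 1, ] <- 4 + 1 * (z - z[2])
  f <- field_map(vals, g)
  profs <- coil_profiles(array(1, c(g$shape, 1)), g)
  m <- full_mask(g)
  ctrl <- shim_control(w = 0.01, include_adjacent_slices = FALSE)
  obj <- slice_objective(c(0), f, profs, m, 2, ctrl)
  expect_equal(obj$mse_term, 12.5)
  # penalty gradients are carried in uT/m: 1 Hz/mm = 23.4866 uT/m
  k <- (1000 / 42.5775)^2
  expect_equal(obj$grad_term, k, tolerance = 1e-12)
  expect_equal(obj$total, 12.5 + 0.01 * k, tolerance = 1e-12)
  # w = 0 reduces the total to the mse term
  obj0 <- slice_objective(c(0), f, profs, m,  2,
                          shim_control(w = 0, include_adjacent_slices = FALSE))
  expect_equal(obj0$total, obj0$mse_term)
  # zero field, zero currents
  zobj <- slice_objective(c(0), uniform_field(g), profs, m, 2, ctrl)
  expect_equal(unlist(zobj), c(total = 0, mse_term = 0, grad_term = 0))
})

test_that("empty masked slices are rejected", {
  g <- small_grid()
  m <- full_mask(g)
  m$weights[, , 3] <- 0
  fx <- small_coil3()
  expect_error(slice_objective(rep(0, 3), uniform_field(g), fx$coil, m, 3),
               "empty")
  expect_error(optimize_slice(uniform_field(g), fx$coil, m, 3), "empty")
})

test_that("zero baseline yields zero currents and zero objective", {
  fx <- small_coil3()
  I <- optimize_slice(uniform_field(fx$grid), fx$coil, full_mask(fx$grid), 4,
                      shim_control(w = 0.01))
  expect_equal(unname(unclass(I))[1:3], c(0, 0, 0), tolerance = 1e-9)
  expect_equal(attr(I, "objective_terms")$total, 0, tolerance = 1e-12)
})

test_that("an in-span baseline is cancelled exactly (bounds inactive)", {
  fx <- small_coil3()
  base <- combine_field(uniform_field(fx$grid), fx$coil, c(-1.7, 0, 0))
  I <- optimize_slice(base, fx$coil, full_mask(fx$grid), 4,
                      shim_control(w = 0, ridge = 1e-12))
  expect_equal(unname(unclass(I))[1:3], c(1.7, 0, 0), tolerance = 1e-7)
  expect_lt(attr(I, "objective_terms")$mse_term, 1e-12)
})

test_that("solver matches a brute-force current grid search on a toy slice", {
  # 2 channels, 6 masked voxels, 0.005 A grid over the box
  set.seed(71)
  g <- grid3d(c(3, 2, 3), c(2, 2, 5))
  profs <- coil_profiles(array(rnorm(prod(g$shape) * 2, sd = 5),
                               c(g$shape, 2)), g)
  base <- field_map(array(rnorm(prod(g$shape), sd = 8), g$shape), g)
  m <- full_mask(g)
  ctrl <- shim_control(w = 0.01, include_adjacent_slices = FALSE,
                       ridge = 1e-12)
  I <- optimize_slice(base, profs, m, 2, ctrl)
  got <- attr(I, "objective_terms")$total
  # independent oracle: evaluate the definition on a 0.005 A lattice
  grid_I <- seq(-2.5, 2.5, by = 0.005)
  f0 <- as.vector(base$values[, , 2])
  p1 <- as.vector(profs$profiles[, , 2, 1]); p2 <- as.vector(profs$profiles[, , 2, 2])
  g0 <- as.vector(through_slice_gradient(base, 2)) * (1000 / 42.5775)
  gp1 <- as.vector(through_slice_gradient(
    field_map(profs$profiles[, , , 1], g), 2)) * (1000 / 42.5775)
  gp2 <- as.vector(through_slice_gradient(
    field_map(profs$profiles[, , , 2], g), 2)) * (1000 / 42.5775)
  best <- Inf
  ones <- rep(1, length(grid_I))
  for (i1 in grid_I) {
    mse <- colMeans((outer(f0 + i1 * p1, ones) + outer(p2, grid_I))^2)
    grd <- colMeans((outer(g0 + i1 * gp1, ones) + outer(gp2, grid_I))^2)
    best <- min(best, min(mse + 0.01 * grd))
  }
  expect_lte(got, best + 1e-9)
  expect_lte(best - got, 1e-3)  # grid resolution gap
})

test_that("a huge penalty nulls the through-slice gradient of a ramp", {
  g <- grid3d(c(5, 5, 7), c(4, 4, 5))
  sh <- sh_basis(g, 1)
  zonly <- coil_profiles(sh$profiles[, , , match("z", sh$names), drop = FALSE],
                         g)
  base <- ramp_field(g, 2.5)
  ctrl0 <- shim_control(w = 0, channel_bound_A = 1e4, total_bound_A = 9e4,
                        ridge = 1e-12)
  ctrlP <- shim_control(w = 1e6, channel_bound_A = 1e4, total_bound_A = 9e4,
                        ridge = 1e-12)
  m <- full_mask(g)
  g_before <- slice_objective(0, base, zonly, m, 4, ctrl0)$grad_term
  I <- optimize_slice(base, zonly, m, 4, ctrlP)
  g_after <- attr(I, "objective_terms")$grad_term
  expect_lt(g_after, 1e-6 * g_before)
})

test_that("slice solutions obey the current constraints and never lose to zero", {
  fx <- small_coil3()
  set.seed(72)
  ctrl <- shim_control(w = 0.01, channel_bound_A = 0.5, total_bound_A = 1.0)
  for (rep in 1:5) {
    base <- field_map(array(rnorm(prod(fx$grid$shape), sd = 60),
                            fx$grid$shape), fx$grid)
    I <- optimize_slice(base, fx$coil, full_mask(fx$grid), 4, ctrl)
    expect_true(max(abs(I)) <= 0.5 + 1e-6)
    expect_true(sum(abs(I)) <= 1.0 + 1e-6)
    tm <- attr(I, "objective_terms")
    z0 <- slice_objective(rep(0, 3), base, fx$coil, full_mask(fx$grid), 4, ctrl)
    expect_lte(tm$total, z0$total + 1e-9)
  }
})

test_that("w = 0 solutions do not depend on the gradient stencil", {
  fx <- small_coil3()
  base <- random_smooth_field(fx$grid, 73)
  f1 <- shim_fit(base, fx$coil, full_mask(fx$grid), w = 0,
                 control = shim_control(slice_thickness_mm = 5))
  f2 <- shim_fit(base, fx$coil, full_mask(fx$grid), w = 0,
                 control = shim_control(slice_thickness_mm = 2.5))
  expect_equal(f1$currents, f2$currents, tolerance = 1e-10)
})

test_that("dynamic solutions are local: far-away planes do not matter", {
  fx <- small_coil3()
  base <- random_smooth_field(fx$grid, 74)
  f1 <- shim_fit(base, fx$coil, full_mask(fx$grid), slices = 4, w = 0.01)
  pert <- base
  pert$values[, , 7] <- pert$values[, , 7] + 300  # >= 2 slices away
  pert$values[, , 1] <- pert$values[, , 1] - 150
  f2 <- shim_fit(pert, fx$coil, full_mask(fx$grid), slices = 4, w = 0.01)
  expect_equal(f1$currents, f2$currents, tolerance = 1e-10)
})

test_that("volume shim is the pooled optimum and dynamic can only improve", {
  fx <- small_coil3()
  base <- random_smooth_field(fx$grid, 75)
  m <- full_mask(fx$grid)
  ctrl <- shim_control(w = 0, include_adjacent_slices = FALSE, ridge = 1e-9)
  vol <- shim_fit(base, fx$coil, m, method = "volume", control = ctrl)
  dyn <- shim_fit(base, fx$coil, m, control = ctrl)
  # pooled MSE at the volume optimum beats random feasible current vectors
  set.seed(76)
  pooled_mse <- function(I) {
    f <- combine_field(base, fx$coil, I)
    mean(f$values^2)
  }
  vol_mse <- pooled_mse(vol$currents[1, ])
  for (k in 1:10) expect_lte(vol_mse, pooled_mse(runif(3, -2.5, 2.5)) + 1e-9)
  # slice-wise relaxation can only help the mean per-slice MSE
  expect_gte(mean(vol$objective$mse_term) + 1e-9, mean(dyn$objective$mse_term))
})

test_that("fit methods expose currents, fields, residuals and predictions", {
  fx <- small_coil3()
  base <- random_smooth_field(fx$grid, 77)
  m <- cylindrical_mask(cbind(rep(22, 7), rep(22, 7)), 30, fx$grid)
  fit <- shim_fit(base, fx$coil, m, w = 0.01)
  expect_s3_class(fit, "shim_fit")
  expect_equal(dim(coef(fit)), c(7L, 3L))
  eff <- fitted(fit)
  expect_s3_class(eff, "field_map")
  # slice planes of the effective field follow each slice's own currents
  s <- 3
  manual <- combine_field(base, fx$coil, coef(fit)[s, ])$values[, , s]
  expect_equal(eff$values[, , s], manual, tolerance = 1e-12)
  res <- residuals(fit)
  expect_true(all(is.na(res$values[m$weights == 0])))
  rmse <- predict(fit, type = "rmse")
  expect_equal(unname(rmse[s]), slice_rmse(eff, m, s), tolerance = 1e-12)
  sl <- predict(fit, type = "loss", acq = acq_params(noise_sigma = 0))
  expect_s3_class(sl, "signal_loss_map")
  summ <- summary(fit)
  expect_true(summ$constraints_ok)
  expect_output(print(fit), "Shim fit")
})
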
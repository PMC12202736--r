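test_that("phase dispersion follows its closed form and is multilinear", {
  expect_equal(phase_dispersion(0, 5, 0.032), 0)
  expect_equal(phase_dispersion(1, 5, 0.032), 2 * pi * 0.16, tolerance = 1e-12)
  set.seed(81)
  g <- runif(5, -3, 3); dz <- runif(5, 1, 8); te <- runif(5, 0.01, 0.06)
  expect_equal(phase_dispersion(2 * g, dz, te), 2 * phase_dispersion(g, dz, te))
  expect_equal(phase_dispersion(g, 2 * dz, te), 2 * phase_dispersion(g, dz, te))
  expect_equal(phase_dispersion(g, dz, 2 * te), 2 * phase_dispersion(g, dz, te))
})

test_that("signal loss reproduces the sinc closed forms", {
  expect_equal(signal_loss(0), 0)
  expect_equal(signal_loss(2 * pi), 1)                      # sin(pi) = 0
  expect_equal(signal_loss(pi), 1 - 2 / pi, tolerance = 1e-12)
  # even in phi
  phis <- seq(-3 * pi, 3 * pi, length.out = 61)
  expect_equal(signal_loss(phis), signal_loss(-phis), tolerance = 1e-14)
  # continuous at zero: Taylor expansion L = phi^2/24 - phi^4/1920 + ...
  # (phi not too small, so the check is not drowned by double-precision
  # cancellation in 1 - sinc)
  small <- 10^seq(-2, -0.5, length.out = 7)
  expect_lt(max(abs(signal_loss(small) - small^2 / 24) /
                  (small^4 / 1920)), 1.1)
  # increasing on [0, 2*pi]
  expect_true(all(diff(signal_loss(seq(0, 2 * pi, length.out = 200))) > 0))
  # global bound 1 - min(sinc)
  expect_lt(max(signal_loss(seq(0, 50, by = 0.01))), 1.2173)
})

test_that("signal-loss maps agree with the scalar operations", {
  g <- grid3d(c(6, 6, 7), c(4, 4, 5))
  acq <- acq_params(te_s = 0.032, slice_thickness_mm = 5)
  # zero field: no loss anywhere
  sl0 <- predict_signal_loss(uniform_field(g), acq)
  expect_equal(max(abs(sl0$L), na.rm = TRUE), 0)
  # pure ramp g = 2 Hz/mm: spatially constant loss equal to the scalar op
  sl <- predict_signal_loss(ramp_field(g, 2), acq, slices = 2:6)
  expected <- signal_loss(phase_dispersion(2, 5, 0.032))
  vals <- sl$L[, , 2:6]
  expect_equal(max(abs(vals - expected)), 0, tolerance = 1e-12)
  # exact shim cancellation of the ramp zeroes the loss (interior slices)
  sh <- sh_basis(g, 1)
  zch <- coil_profiles(sh$profiles[, , , match("z", sh$names), drop = FALSE], g)
  slope_per_A <- through_slice_gradient(field_map(zch$profiles[, , , 1], g), 4)[1, 1]
  shimmed <- combine_field(ramp_field(g, 2), zch, -2 / slope_per_A)
  slc <- predict_signal_loss(shimmed, acq, slices = 2:6)
  expect_equal(max(abs(slc$L[, , 2:6])), 0, tolerance = 1e-9)
})

test_that("EPI simulation: no field, no noise reproduces the template", {
  ph <- make_phantom(phantom_spec(grid = grid3d(c(16, 16, 5), c(4, 4, 5))))
  acq <- acq_params(n_volumes = 3, noise_sigma = 0)
  ts <- simulate_epi(ph$labelmap, uniform_field(ph$grid), acq)
  expect_equal(dim(ts$data), c(16, 16, 5, 3))
  template <- array(0, ph$grid$shape)
  template[ph$labelmap == 1L] <- 0.4
  template[ph$labelmap == 2L] <- 1.0
  for (v in 1:3) expect_equal(ts$data[, , , v], template, tolerance = 1e-12)
})

test_that("uniform through-slice gradient attenuates by |sinc(phi/2)|", {
  ph <- make_phantom(phantom_spec(grid = grid3d(c(12, 12, 7), c(4, 4, 5))))
  acq <- acq_params(n_volumes = 1, noise_sigma = 0,
                    total_readout_time_s = 1e-12)  # negligible distortion
  gz <- 1.2
  ts <- simulate_epi(ph$labelmap, ramp_field(ph$grid, gz), acq)
  att <- abs(1 - signal_loss(phase_dispersion(gz, 5, acq$te_s)))
  cord <- ph$labelmap[, , 4] == 2L
  got <- ts$data[, , 4, 1][cord]
  expect_equal(got, rep(1.0 * att, sum(cord)), tolerance = 1e-9)
  # mean in-cord signal decreases monotonically with the imposed gradient
  sig <- vapply(seq(0, 1 / (5 * 0.032) , length.out = 5), function(gg) {
    t1 <- simulate_epi(ph$labelmap, ramp_field(ph$grid, gg), acq)
    mean(t1$data[, , 4, 1][cord])
  }, numeric(1))
  expect_true(all(diff(sig) < 0))
})

test_that("off-resonance shifts columns by f * readout * N_pe voxels", {
  g <- grid3d(c(10, 64, 3), c(2, 2, 5))
  lab <- array(0L, g$shape)
  lab[4:6, 30:33, ] <- 2L
  # f * trt * N_pe = 10 * 0.0046875 * 64 = 3.0 voxels exactly
  acq <- acq_params(n_volumes = 1, noise_sigma = 0,
                    total_readout_time_s = 0.0046875, pe_axis = 2)
  ts <- simulate_epi(lab, uniform_field(g, 10), acq)
  template <- array(0, g$shape); template[lab == 2L] <- 1
  shifted <- array(0, g$shape)
  shifted[, 4:64, ] <- template[, 1:61, ]
  expect_equal(ts$data[, , , 1], shifted, tolerance = 1e-9)
  # cross-correlation peak at the predicted lag
  cc <- vapply(0:6, function(lag)
    sum(ts$data[, (1 + lag):64, 2, 1] * template[, 1:(64 - lag), 2]),
    numeric(1))
  expect_equal(which.max(cc) - 1, 3)
})

test_that("EPI noise is Rician, seeded and reproducible", {
  ph <- make_phantom(phantom_spec(grid = grid3d(c(8, 8, 4), c(4, 4, 5))))
  acq <- acq_params(n_volumes = 4, noise_sigma = 0.1, seed = 9)
  t1 <- simulate_epi(ph$labelmap, uniform_field(ph$grid), acq)
  t2 <- simulate_epi(ph$labelmap, uniform_field(ph$grid), acq)
  expect_identical(t1$data, t2$data)
  acq$seed <- 10L
  t3 <- simulate_epi(ph$labelmap, uniform_field(ph$grid), acq)
  expect_false(identical(t1$data, t3$data))
  expect_true(all(t1$data >= 0))  # magnitude data
})
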
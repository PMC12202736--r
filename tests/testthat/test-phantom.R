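test_that("all field sources off gives exactly the background polynomial", {
  g <- grid3d(c(10, 10, 6), c(4, 4, 5))
  spec0 <- phantom_spec(grid = g, disc_amplitude_hz = 0,
                        caudal_gradient_hz_per_mm = 0,
                        background_poly_coeffs = c(const = 0))
  ph0 <- make_phantom(spec0)
  expect_true(all(ph0$baseline_field$values == 0))

  co <- c(const = 7, x = 0.25, z = -0.5, yy = 0.01)
  ph <- make_phantom(phantom_spec(grid = g, disc_amplitude_hz = 0,
                                  caudal_gradient_hz_per_mm = 0,
                                  background_poly_coeffs = co))
  x <- axis_coords(g, 1) - mean(range(axis_coords(g, 1)))
  y <- axis_coords(g, 2) - mean(range(axis_coords(g, 2)))
  z <- axis_coords(g, 3) - mean(range(axis_coords(g, 3)))
  expected <- outer(outer(7 + 0.25 * x, 0.01 * y^2, "+"), -0.5 * z, "+")
  expect_equal(ph$baseline_field$values, expected, tolerance = 1e-12)
})

test_that("field composition is additive across source terms", {
  g <- grid3d(c(12, 12, 9), c(4, 4, 5))
  args <- list(grid = g, background_poly_coeffs = c(const = 5, z = 0.2),
               disc_amplitude_hz = 20, caudal_gradient_hz_per_mm = 3,
               caudal_start_slice = 5)
  all_on <- make_phantom(do.call(phantom_spec, args))
  one <- function(keep) {
    a <- args
    if (keep != "bg") a$background_poly_coeffs <- c(const = 0)
    if (keep != "disc") a$disc_amplitude_hz <- 0
    if (keep != "ramp") a$caudal_gradient_hz_per_mm <- 0
    make_phantom(do.call(phantom_spec, a))$baseline_field$values
  }
  expect_equal(all_on$baseline_field$values,
               one("bg") + one("disc") + one("ramp"), tolerance = 1e-12)
})

test_that("caudal ramp yields its exact slope as through-slice gradient", {
  g <- grid3d(c(10, 10, 25), c(4, 4, 5))
  ph <- make_phantom(phantom_spec(grid = g, disc_amplitude_hz = 0,
                                  caudal_gradient_hz_per_mm = 2,
                                  caudal_start_slice = 15,
                                  background_poly_coeffs = c(const = 0)))
  for (s in 1:14) {
    gr <- through_slice_gradient(ph$baseline_field, s)
    cord <- ph$labelmap[, , s] == 2L
    expect_true(any(cord))
    expect_equal(mean(gr[cord]), 2.0, tolerance = 1e-9)
  }
  # above the boundary the ramp contributes nothing
  gr_up <- through_slice_gradient(ph$baseline_field, 20)
  expect_equal(max(abs(gr_up)), 0, tolerance = 1e-9)
})

test_that("phantom generation is a pure function of spec and seed", {
  g <- grid3d(c(8, 8, 5), c(4, 4, 5))
  a <- make_phantom(phantom_spec(grid = g, noise_sigma = 2, seed = 7))
  b <- make_phantom(phantom_spec(grid = g, noise_sigma = 2, seed = 7))
  c <- make_phantom(phantom_spec(grid = g, noise_sigma = 2, seed = 8))
  expect_identical(a$baseline_field$values, b$baseline_field$values)
  expect_false(identical(a$baseline_field$values, c$baseline_field$values))
})

test_that("cord lies inside the body and the centerline inside the cord", {
  ph <- make_phantom(phantom_spec(grid = grid3d(c(32, 32, 13), c(4, 4, 5))))
  expect_true(all(ph$labelmap[ph$labelmap == 2L] > 0))
  # every cord voxel is also body-supported (labelmap 2 implies inside body)
  body_or_cord <- ph$labelmap > 0L
  expect_true(all((ph$labelmap == 2L) <= body_or_cord))
  g <- ph$grid
  for (s in seq_len(g$shape[3])) {
    i <- round((ph$centerline[s, 1] - g$origin_mm[1]) / g$voxel_size_mm[1]) + 1
    j <- round((ph$centerline[s, 2] - g$origin_mm[2]) / g$voxel_size_mm[2]) + 1
    expect_equal(ph$labelmap[i, j, s], 2L)
  }
})

test_that("degenerate grids are rejected", {
  expect_error(phantom_spec(grid = grid3d(c(8, 8, 2), c(4, 4, 5))), "at least 3")
})

test_that("level table covers slices contiguously, rostral to caudal", {
  lt <- default_level_table(25)
  expect_equal(nrow(lt), 8)
  expect_equal(as.character(lt$level[1]), "C3")
  expect_equal(as.character(lt$level[8]), "T3")
  covered <- unlist(Map(seq, lt$first_slice, lt$last_slice))
  expect_equal(sort(covered), 1:25)          # disjoint and complete
  expect_true(all(diff(lt$first_slice) < 0)) # ordered rostral -> caudal
})

test_that("dual-echo simulation encodes the field in the phase difference", {
  g <- grid3d(c(4, 4, 3), c(2, 2, 5))
  # zero field, no noise: both echoes real positive
  de0 <- simulate_dual_echo(uniform_field(g, 0))
  expect_true(all(Im(de0$echo1) == 0 & Re(de0$echo1) > 0))
  expect_true(all(Arg(de0$echo2) == 0))
  # 100 Hz: phase difference 2*pi*100*dTE everywhere
  de <- simulate_dual_echo(uniform_field(g, 100), 0.00268, 0.00492)
  dphi <- Arg(Conj(de$echo1) * de$echo2)
  expect_equal(unname(dphi[1, 1, 1]), 2 * pi * 100 * 0.00224,
               tolerance = 1e-9)
  expect_equal(max(abs(dphi - dphi[1, 1, 1])), 0, tolerance = 1e-12)
  # seeding contract
  n1 <- simulate_dual_echo(uniform_field(g, 50), noise_sigma = 0.1, seed = 3)
  n2 <- simulate_dual_echo(uniform_field(g, 50), noise_sigma = 0.1, seed = 3)
  n3 <- simulate_dual_echo(uniform_field(g, 50), noise_sigma = 0.1, seed = 4)
  expect_identical(n1$echo1, n2$echo1)
  expect_false(identical(n1$echo1, n3$echo1))
})
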
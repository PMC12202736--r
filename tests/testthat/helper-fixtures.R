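# Shared fixtures, built lazily and cached for the whole test run.

.fx <- new.env(parent = emptyenv())

fx_cache <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# small grid for fast unit tests
small_grid <- function() grid3d(c(12, 12, 7), c(4, 4, 5))

# uniform field helper
uniform_field <- function(grid, value = 0) {
  field_map(array(value, grid$shape), grid)
}

# field linear in z: f = a * z + b
ramp_field <- function(grid, a, b = 0) {
  z <- axis_coords(grid, 3)
  vals <- array(rep(a * z + b, each = grid$shape[1] * grid$shape[2]),
                grid$shape)
  field_map(vals, grid)
}

# full-coverage binary mask
full_mask <- function(grid) shim_mask(array(1, grid$shape), grid)

# random smooth-ish field for interpolation tests
random_smooth_field <- function(grid, seed = 1) {
  set.seed(seed)
  x <- axis_coords(grid, 1); y <- axis_coords(grid, 2); z <- axis_coords(grid, 3)
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  X <- array(rep(x, times = ny * nz), grid$shape)
  Y <- array(rep(rep(y, each = nx), times = nz), grid$shape)
  Z <- array(rep(z, each = nx * ny), grid$shape)
  co <- rnorm(7, sd = c(10, 0.5, 0.5, 0.5, 0.02, 0.02, 0.02))
  vals <- co[1] + co[2] * X + co[3] * Y + co[4] * Z +
    co[5] * X * Y + co[6] * Y * Z + co[7] * X * Z +
    3 * sin(X / 11) * cos(Y / 13) * sin(Z / 17)
  field_map(vals, grid)
}

# -- study-scale fixture: the default 25-slice phantom experiment ----------
# (built once; used by the acceptance tests)

study_fixture <- function() {
  fx_cache("study", function() {
    g_fine <- grid3d(c(64, 64, 97), c(2, 2, 1.25))
    ph <- make_phantom(phantom_spec(grid = g_fine, caudal_start_slice = 13))
    m40 <- cylindrical_mask(ph$centerline, 40, g_fine)
    m25 <- cylindrical_mask(ph$centerline, 25, g_fine)
    sh <- sh_basis(g_fine, 2)
    vf <- shim_fit(ph$baseline_field, sh, m40, method = "volume",
                   control = shim_control(w = 0, channel_bound_A = 1e3,
                                          total_bound_A = 9e3, ridge = 1e-9))
    base <- combine_field(ph$baseline_field, sh, vf$currents[1, ])
    coil <- array_profiles(default_loop_layout(g_fine), g_fine)
    list(grid = g_fine, phantom = ph, mask40 = m40, mask25 = m25,
         baseline = base, coil = coil, slices = seq(1L, 97L, by = 4L))
  })
}

# dynamic fits of the study fixture across the published w grid, at the
# pure (tie-break ridge) objective
study_fits_pure <- function() {
  fx_cache("study_fits_pure", function() {
    fx <- study_fixture()
    lapply(c(w0 = 0, `w1e-04` = 1e-4, `w0.01` = 0.01, w1 = 1), function(w)
      shim_fit(fx$baseline, fx$coil, fx$mask25, slices = fx$slices, w = w,
               control = shim_control(slice_thickness_mm = 5,
                                      ridge = 1e-12)))
  })
}

# full end-to-end pipeline at the default study conditions
pipeline_result <- function() {
  fx_cache("pipeline", function() run_pipeline(pipeline_config(seed = 1L)))
}

# 3-channel loop coil on a small grid (well-conditioned span)
small_coil3 <- function() {
  fx_cache("coil3", function() {
    g <- small_grid()
    loops <- list(
      loop_geometry(c(24, -30, 5), 30, normal = c(0, 1, 0), n_segments = 64),
      loop_geometry(c(24, -30, 20), 30, normal = c(0, 1, 0.3), n_segments = 64),
      loop_geometry(c(-10, -30, 12), 30, normal = c(0.3, 1, 0), n_segments = 64))
    list(grid = g, coil = array_profiles(loops, g))
  })
}
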
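#' Synthetic spinal-cord phantom specification
#'
#' Parameters of the seeded phantom generator. The phantom emulates the field
#' environment of the cervico-thoracic spinal cord (C3-T3): a curved cord
#' inside a body ellipse, a smooth low-order background field, a spatially
#' periodic perturbation near the vertebral discs (bone-tissue interfaces),
#' and a strong caudal through-slice gradient where the field map approaches
#' the lungs. Slice index 1 is the most caudal slice (T3); the slice index
#' increases rostrally (towards C3), and z increases with slice index.
#'
#' Defaults: a 64 x 64 x 25 grid at 2 x 2 x 5 mm (25 axial slices covering
#' C3-T3), cord radius 4 mm, a 6 mm anterior-posterior bow, 25 Hz disc
#' perturbations every 20 mm sourced 12 mm anterior to the cord (in-cord
#' through-slice gradients of a few Hz/mm, mild dephasing at
#' TE = 32 ms / 5 mm slices), and a steep lung-proximity ramp of 10 Hz/mm
#' confined below the T2 level, giving near-complete baseline through-slice
#' dephasing on the lowest slices while the total field stays inside the
#' +/-223 Hz unambiguous range of the dual-echo field map. These amplitudes
#' give the canonical cervico-thoracic pattern - minimal signal loss from C4
#' to T1, severe loss at T2/T3 - and are plausible for 3 T, but are not
#' claimed to match any in-vivo dataset.
#'
#' @param grid a [grid3d()]; every dimension must be >= 3 so that spatial
#'   gradients are defined.
#' @param cord_radius_mm cord radius (mm).
#' @param centerline_amplitude_mm amplitude of the anterior-posterior bow of
#'   the cord centerline (mm, >= 0).
#' @param disc_period_mm spatial period of the disc perturbation along z (mm;
#'   default 20, one vertebral body + disc).
#' @param disc_amplitude_hz peak amplitude of the disc perturbation at its
#'   source (Hz, >= 0).
#' @param disc_offset_mm anterior offset of the disc source line from the
#'   cord centerline (mm); the bone-tissue interface sits at the posterior
#'   tip of the disc, anterior to the cord, so the perturbation peaks there
#'   and decays across the cord.
#' @param disc_sigma_mm in-plane Gaussian decay length of the disc
#'   perturbation away from its source line (mm).
#' @param caudal_gradient_hz_per_mm slope of the caudal (lung-proximity)
#'   linear ramp (Hz/mm).
#' @param caudal_start_slice 1-based slice index below which the caudal ramp
#'   applies (the "T1" boundary); the ramp is
#'   `g * (z - z_start)` for `z < z_start`, zero above.
#' @param background_poly_coeffs named numeric vector of low-order polynomial
#'   coefficients (Hz, Hz/mm, Hz/mm^2) over coordinates centred on the grid;
#'   recognised names: `const, x, y, z, xx, yy, zz, xy, xz, yz`.
#' @param noise_sigma standard deviation of iid Gaussian field noise (Hz).
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = grid3d(c(64, 64, 25), c(2, 2, 5)),
                         cord_radius_mm = 4,
                         centerline_amplitude_mm = 6,
                         disc_period_mm = 20,
                         disc_amplitude_hz = 25,
                         disc_offset_mm = 12,
                         disc_sigma_mm = 10,
                         caudal_gradient_hz_per_mm = 10,
                         caudal_start_slice = 4,
                         background_poly_coeffs = c(const = 15, x = 0.1,
                                                    y = -0.15, z = 0.25),
                         noise_sigma = 0,
                         seed = 1L) {
  stopifnot(inherits(grid, "grid3d"))
  if (any(grid$shape < 3L))
    stop("phantom grid needs at least 3 voxels per axis for gradients")
  stopifnot(cord_radius_mm > 0, centerline_amplitude_mm >= 0,
            disc_period_mm > 0, disc_amplitude_hz >= 0, disc_sigma_mm > 0,
            disc_offset_mm >= 0, noise_sigma >= 0)
  caudal_start_slice <- as.integer(caudal_start_slice)
  stopifnot(caudal_start_slice >= 1, caudal_start_slice <= grid$shape[3])
  known <- c("const", "x", "y", "z", "xx", "yy", "zz", "xy", "xz", "yz")
  if (length(background_poly_coeffs) &&
      !all(names(background_poly_coeffs) %in% known))
    stop("unknown background polynomial term; allowed: ",
         paste(known, collapse = ", "))
  structure(list(grid = grid, cord_radius_mm = cord_radius_mm,
                 centerline_amplitude_mm = centerline_amplitude_mm,
                 disc_period_mm = disc_period_mm,
                 disc_amplitude_hz = disc_amplitude_hz,
                 disc_offset_mm = disc_offset_mm,
                 disc_sigma_mm = disc_sigma_mm,
                 caudal_gradient_hz_per_mm = caudal_gradient_hz_per_mm,
                 caudal_start_slice = caudal_start_slice,
                 background_poly_coeffs = background_poly_coeffs,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# run code under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Vertebral level table for a stack of axial slices
#'
#' Distributes `nz` contiguous axial slices across vertebral levels C3-T3
#' (rostral to caudal), in near-equal contiguous runs; any remainder slices
#' are given to the caudal-most levels. Slice 1 is the most caudal.
#'
#' @param nz number of slices.
#' @return A data frame with columns `level` (ordered rostral to caudal),
#'   `first_slice`, `last_slice` (inclusive 1-based slice range,
#'   `first_slice <= last_slice`).
#' @export
default_level_table <- function(nz) {
  nz <- as.integer(nz)
  stopifnot(nz >= 1)
  names8 <- c("C3", "C4", "C5", "C6", "C7", "T1", "T2", "T3")
  k <- min(nz, 8L)
  nm <- names8[seq_len(k)]
  sizes <- rep(nz %/% k, k)
  r <- nz %% k
  if (r > 0) sizes[(k - r + 1):k] <- sizes[(k - r + 1):k] + 1L
  hi <- nz - c(0L, cumsum(sizes))[seq_len(k)]
  lo <- hi - sizes + 1L
  data.frame(level = factor(nm, levels = nm), first_slice = lo,
             last_slice = hi, stringsAsFactors = FALSE)
}

#' Generate the synthetic spinal-cord phantom
#'
#' Builds the cord label map, centerline, baseline B0 field and vertebral
#' level table from a [phantom_spec()]. The baseline field is the sum of the
#' background polynomial, the disc term
#' `A * sin(2 pi z / period) * exp(-max(0, r - R)^2 / (2 sigma_r^2))`
#' (full amplitude inside the cord, Gaussian radial decay outside), the
#' caudal ramp, and optional iid Gaussian noise. Generation is a pure
#' function of (spec, seed) and the three deterministic terms are additive.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `spinal_phantom`: list with `spec`, `grid`,
#'   `labelmap` (integer array: 0 outside body, 1 body, 2 cord),
#'   `centerline` (nz x 2 matrix of (x, y) mm per slice),
#'   `baseline_field` (a [field_map()]), `level_table`.
#' @examples
#' ph <- make_phantom(phantom_spec(grid3d(c(16, 16, 9), c(4, 4, 5))))
#' ph$level_table
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  if (any(g$shape < 3L))
    stop("phantom grid needs at least 3 voxels per axis for gradients")
  x <- axis_coords(g, 1); y <- axis_coords(g, 2); z <- axis_coords(g, 3)
  nx <- g$shape[1]; ny <- g$shape[2]; nz <- g$shape[3]
  cx <- mean(range(x)); cy <- mean(range(y)); cz <- mean(range(z))
  zext <- max(diff(range(z)), 1)
  frac <- (z - min(z)) / zext
  centerline <- cbind(x_mm = rep(cx, nz),
                      y_mm = cy + spec$centerline_amplitude_mm * sin(pi * frac))

  X <- array(rep(x, times = ny * nz), g$shape)
  Y <- array(rep(rep(y, each = nx), times = nz), g$shape)
  Z <- array(rep(z, each = nx * ny), g$shape)

  # in-plane distance to the slice's centerline point
  CLX <- array(rep(centerline[, 1], each = nx * ny), g$shape)
  CLY <- array(rep(centerline[, 2], each = nx * ny), g$shape)
  r_inplane <- sqrt((X - CLX)^2 + (Y - CLY)^2)

  # body: in-plane ellipse around the grid center, constant along z
  ax <- 0.38 * diff(range(x)) + g$voxel_size_mm[1]
  ay <- 0.32 * diff(range(y)) + g$voxel_size_mm[2]
  body <- ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 <= 1
  cord <- r_inplane <= spec$cord_radius_mm
  labelmap <- array(0L, g$shape)
  labelmap[body] <- 1L
  labelmap[cord] <- 2L

  co <- spec$background_poly_coeffs
  cf <- function(nm) if (nm %in% names(co)) co[[nm]] else 0
  Xc <- X - cx; Yc <- Y - cy; Zc <- Z - cz
  fld <- cf("const") + cf("x") * Xc + cf("y") * Yc + cf("z") * Zc +
    cf("xx") * Xc^2 + cf("yy") * Yc^2 + cf("zz") * Zc^2 +
    cf("xy") * Xc * Yc + cf("xz") * Xc * Zc + cf("yz") * Yc * Zc

  if (spec$disc_amplitude_hz > 0) {
    # source line anterior (+y) of the centerline; Gaussian in-plane decay
    d2_src <- (X - CLX)^2 + (Y - (CLY + spec$disc_offset_mm))^2
    fld <- fld + spec$disc_amplitude_hz * sin(2 * pi * Z / spec$disc_period_mm) *
      exp(-d2_src / (2 * spec$disc_sigma_mm^2))
  }
  if (spec$caudal_gradient_hz_per_mm != 0) {
    z_start <- slice_z(g, spec$caudal_start_slice)
    fld <- fld + spec$caudal_gradient_hz_per_mm * pmin(0, Z - z_start)
  }
  if (spec$noise_sigma > 0) {
    fld <- fld + with_seed(spec$seed,
                           array(stats::rnorm(prod(g$shape), 0, spec$noise_sigma),
                                 g$shape))
  }
  structure(list(spec = spec, grid = g, labelmap = labelmap,
                 centerline = centerline,
                 baseline_field = field_map(fld, g),
                 level_table = default_level_table(nz)),
            class = "spinal_phantom")
}

#' @export
print.spinal_phantom <- function(x, ...) {
  cat("<spinal_phantom> ", paste(x$grid$shape, collapse = " x "),
      " voxels; ", sum(x$labelmap == 2L), " cord voxels; field range [",
      paste(format(range(x$baseline_field$values), digits = 4),
            collapse = ", "), "] Hz\n", sep = "")
  invisible(x)
}

#' Simulate dual-echo complex GRE data from a field
#'
#' Each echo is `magnitude * exp(2i pi f te_k)` plus complex Gaussian noise.
#' For a phantom input the magnitude is 1 inside the body and a small epsilon
#' outside; invalid field voxels get zero magnitude.
#'
#' @param x a [field_map()] or a `spinal_phantom`.
#' @param te1_s,te2_s echo times (s), `te2_s > te1_s > 0`; defaults are the
#'   standard dual-echo field-map times 2.68 / 4.92 ms.
#' @param noise_sigma standard deviation of the complex Gaussian noise per
#'   real/imaginary component.
#' @param seed integer seed for the noise.
#' @param magnitude optional numeric array of spin density (defaults to 1
#'   everywhere for a plain field, body-based for a phantom).
#' @param outside_epsilon magnitude outside the body for phantom input.
#' @return An object of class `dual_echo`: list with complex arrays `echo1`,
#'   `echo2`, plus `grid`, `te1_s`, `te2_s`.
#' @export
simulate_dual_echo <- function(x, te1_s = 0.00268, te2_s = 0.00492,
                               noise_sigma = 0, seed = 1L, magnitude = NULL,
                               outside_epsilon = 0.01) {
  if (inherits(x, "spinal_phantom")) {
    if (is.null(magnitude))
      magnitude <- ifelse(x$labelmap > 0L, 1, outside_epsilon)
    field <- x$baseline_field
  } else if (inherits(x, "field_map")) {
    field <- x
    if (is.null(magnitude)) magnitude <- array(1, field$grid$shape)
  } else stop("x must be a field_map or spinal_phantom")
  if (!(te2_s > te1_s && te1_s > 0))
    stop("echo times must satisfy te2_s > te1_s > 0")
  stopifnot(noise_sigma >= 0)
  g <- field$grid
  magnitude <- array(as.numeric(magnitude), g$shape)
  f <- field$values
  magnitude[is.na(f)] <- 0
  f[is.na(f)] <- 0
  mk_echo <- function(te) magnitude * exp(2i * pi * f * te)
  e1 <- mk_echo(te1_s); e2 <- mk_echo(te2_s)
  if (noise_sigma > 0) {
    nvox <- prod(g$shape)
    noise <- with_seed(seed, stats::rnorm(4 * nvox, 0, noise_sigma))
    e1 <- e1 + array(complex(real = noise[1:nvox],
                             imaginary = noise[nvox + 1:nvox]), g$shape)
    e2 <- e2 + array(complex(real = noise[2 * nvox + 1:nvox],
                             imaginary = noise[3 * nvox + 1:nvox]), g$shape)
  }
  structure(list(echo1 = e1, echo2 = e2, grid = g,
                 te1_s = te1_s, te2_s = te2_s),
            class = "dual_echo")
}
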
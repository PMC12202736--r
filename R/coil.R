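MU0 <- 4 * pi * 1e-7          # T m / A
GAMMA_HZ_PER_T <- 42.5775e6   # gyromagnetic ratio / 2 pi, Hz / T

#' Circular shim loop geometry
#'
#' @param center_mm loop center (x, y, z) in mm.
#' @param radius_mm loop radius (mm, > 0).
#' @param normal loop normal vector (normalized internally; must be nonzero).
#' @param n_segments number of polygon segments approximating the loop
#'   (>= 8; the on-axis field converges to the closed form as 1/n^2).
#' @return An object of class `loop_geometry`.
#' @export
loop_geometry <- function(center_mm, radius_mm, normal = c(0, 0, 1),
                          n_segments = 64L) {
  stopifnot(length(center_mm) == 3, radius_mm > 0, length(normal) == 3)
  n_segments <- as.integer(n_segments)
  if (n_segments < 8L) stop("n_segments must be >= 8")
  nrm <- sqrt(sum(normal^2))
  if (nrm < 1e-12) stop("loop normal must be a nonzero vector")
  structure(list(center_mm = as.numeric(center_mm),
                 radius_mm = as.numeric(radius_mm),
                 normal = as.numeric(normal) / nrm,
                 n_segments = n_segments),
            class = "loop_geometry")
}

#' Field profile of a single loop (Biot-Savart)
#'
#' Computes the z-component of the magnetic field of a polygonal
#' approximation of the loop carrying 1 A, at every voxel center, converted
#' to off-resonance via `f = (gamma / 2 pi) * B_z` with gamma / 2 pi =
#' 42.5775 MHz/T. Only B_z contributes to off-resonance (standard MR
#' convention); transverse components are discarded. Voxels closer to the
#' wire than `1e-3 * radius` are flagged invalid (the field diverges there).
#'
#' @param loop a [loop_geometry()].
#' @param grid a [grid3d()].
#' @return A [field_map()] in Hz/A (invalid voxels `NA`).
#' @export
loop_profile <- function(loop, grid) {
  stopifnot(inherits(loop, "loop_geometry"), inherits(grid, "grid3d"))
  pts <- grid_centers(grid) * 1e-3            # m
  ctr <- loop$center_mm * 1e-3
  a <- loop$radius_mm * 1e-3
  nvec <- loop$normal
  # orthonormal in-plane basis
  ref <- if (abs(nvec[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * nvec) * nvec
  u <- u / sqrt(sum(u^2))
  v <- c(nvec[2] * u[3] - nvec[3] * u[2],
         nvec[3] * u[1] - nvec[1] * u[3],
         nvec[1] * u[2] - nvec[2] * u[1])
  ns <- loop$n_segments
  th <- 2 * pi * (seq_len(ns + 1) - 1) / ns
  ring <- cbind(ctr[1] + a * (cos(th) * u[1] + sin(th) * v[1]),
                ctr[2] + a * (cos(th) * u[2] + sin(th) * v[2]),
                ctr[3] + a * (cos(th) * u[3] + sin(th) * v[3]))
  bz <- numeric(nrow(pts))
  for (s in seq_len(ns)) {
    mid <- (ring[s, ] + ring[s + 1, ]) / 2
    dl <- ring[s + 1, ] - ring[s, ]
    rx <- pts[, 1] - mid[1]; ry <- pts[, 2] - mid[2]; rz <- pts[, 3] - mid[3]
    r3 <- (rx * rx + ry * ry + rz * rz)^1.5
    # z-component of dl x r
    bz <- bz + (dl[1] * ry - dl[2] * rx) / r3
  }
  bz <- bz * MU0 / (4 * pi)                    # tesla per ampere
  hz <- bz * GAMMA_HZ_PER_T
  # invalid where too close to the wire: analytic distance to the circle
  rel <- sweep(pts, 2, ctr)
  h <- rel %*% nvec
  rad2 <- rowSums(rel^2) - h^2
  dist_wire <- sqrt((sqrt(pmax(rad2, 0)) - a)^2 + h^2)
  bad <- dist_wire < 1e-3 * a
  hz[bad] <- NA_real_
  field_map(array(hz, grid$shape), grid)
}

#' Multichannel coil profile set
#'
#' Per-channel field per unit current on a shared grid, Hz/A. The field of
#' current `I` on channel `c` is `I * profile_c` by construction
#' (superposition).
#'
#' @param profiles 4D numeric array (nx, ny, nz, n_channels), Hz/A.
#' @param grid a [grid3d()].
#' @param names character vector of unique channel names.
#' @param meta optional per-channel metadata (e.g. the loop geometries).
#' @return An object of class `coil_profiles`.
#' @export
coil_profiles <- function(profiles, grid, names = NULL, meta = NULL) {
  stopifnot(inherits(grid, "grid3d"))
  d <- dim(profiles)
  if (length(d) == 3L) { profiles <- array(profiles, c(d, 1L)); d <- dim(profiles) }
  stopifnot(length(d) == 4L, identical(as.integer(d[1:3]), grid$shape))
  n <- d[4]
  if (is.null(names)) names <- paste0("ch", seq_len(n))
  if (anyDuplicated(names)) stop("duplicate channel names")
  if (length(names) != n) stop("need one name per channel")
  structure(list(grid = grid, n_channels = as.integer(n),
                 profiles = profiles, names = as.character(names),
                 meta = meta),
            class = "coil_profiles")
}

#' @export
print.coil_profiles <- function(x, ...) {
  cat("<coil_profiles> ", x$n_channels, " channels on ",
      paste(x$grid$shape, collapse = " x "), " voxels\n", sep = "")
  invisible(x)
}

#' Stack loop profiles into a coil array
#'
#' @param loops list of [loop_geometry()].
#' @param grid a [grid3d()].
#' @param names optional channel names (default `loop1..loopN`).
#' @return A [coil_profiles()] (invalid wire-adjacent voxels carry `NA`).
#' @export
array_profiles <- function(loops, grid, names = NULL) {
  stopifnot(is.list(loops), length(loops) >= 1)
  if (is.null(names)) names <- paste0("loop", seq_along(loops))
  prof <- array(NA_real_, c(grid$shape, length(loops)))
  for (i in seq_along(loops))
    prof[, , , i] <- loop_profile(loops[[i]], grid)$values
  coil_profiles(prof, grid, names = names, meta = loops)
}

#' Default 15-loop cervico-thoracic layout
#'
#' Fifteen loops on a posterior cylinder behind the cord: fourteen in two
#' staggered columns covering the rostral (cervical) part of the z extent,
#' and a single caudal loop near the lowest (T2-T3) slices - mirroring shim
#' arrays built for the cervical spine, which are loop-dense rostrally and
#' sparse at the thoracic end. The geometry is a plausible stand-in, not any
#' specific published coil.
#'
#' @param grid a [grid3d()] (used for the z extent and in-plane center).
#' @param n_loops total number of loops (default 15).
#' @param cylinder_radius_mm distance of loop centers from the cord axis
#'   (default 60 mm - the posterior neck surface sits roughly 6 cm from the
#'   cord, and coils further out cannot steer the through-slice gradient at
#'   the cord within realistic current limits).
#' @param loop_radius_mm loop radius.
#' @param n_segments polygon segments per loop.
#' @return list of [loop_geometry()].
#' @export
default_loop_layout <- function(grid, n_loops = 15L, cylinder_radius_mm = 60,
                                loop_radius_mm = 45, n_segments = 64L) {
  stopifnot(inherits(grid, "grid3d"), n_loops >= 2)
  x <- axis_coords(grid, 1); y <- axis_coords(grid, 2); z <- axis_coords(grid, 3)
  cx <- mean(range(x)); cy <- mean(range(y))
  zmin <- min(z); zext <- max(diff(range(z)), 1)
  n_rostral <- n_loops - 1L
  nrows <- ceiling(n_rostral / 2)
  zfrac <- seq(0.35, 1.0, length.out = nrows)
  loops <- vector("list", n_loops)
  k <- 0L
  for (r in seq_len(nrows)) {
    angs <- if (2L * r <= n_rostral) c(-25, 25) else 0
    for (ang in angs) {
      k <- k + 1L
      th <- ang * pi / 180
      ctr <- c(cx + cylinder_radius_mm * sin(th),
               cy - cylinder_radius_mm * cos(th),
               zmin + zfrac[r] * zext)
      loops[[k]] <- loop_geometry(ctr, loop_radius_mm,
                                  normal = c(-sin(th), cos(th), 0),
                                  n_segments = n_segments)
    }
  }
  # single caudal loop
  loops[[n_loops]] <- loop_geometry(c(cx, cy - cylinder_radius_mm,
                                      zmin + 0.1 * zext),
                                    loop_radius_mm, normal = c(0, 1, 0),
                                    n_segments = n_segments)
  loops[seq_len(n_loops)]
}

#' Spherical-harmonic shim basis (orders 0-2)
#'
#' Real solid harmonics evaluated at voxel centers relative to the grid
#' center: `1, x, y, z, xy, zy, 2z^2 - x^2 - y^2, zx, x^2 - y^2` (nine
#' channels at order 2), each normalized to unit root-mean-square over the
#' grid. This emulates a scanner's zeroth- to second-order volume shim.
#'
#' @param grid a [grid3d()].
#' @param max_order 0, 1 or 2.
#' @return A [coil_profiles()] with 1, 4 or 9 channels.
#' @export
sh_basis <- function(grid, max_order = 2L) {
  stopifnot(inherits(grid, "grid3d"), max_order %in% 0:2)
  x <- axis_coords(grid, 1); y <- axis_coords(grid, 2); z <- axis_coords(grid, 3)
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  X <- array(rep(x, times = ny * nz), grid$shape) - mean(range(x))
  Y <- array(rep(rep(y, each = nx), times = nz), grid$shape) - mean(range(y))
  Z <- array(rep(z, each = nx * ny), grid$shape) - mean(range(z))
  chans <- list(f0 = array(1, grid$shape))
  if (max_order >= 1) chans <- c(chans, list(x = X, y = Y, z = Z))
  if (max_order >= 2)
    chans <- c(chans, list(xy = X * Y, zy = Z * Y,
                           z2 = 2 * Z^2 - X^2 - Y^2, zx = Z * X,
                           x2y2 = X^2 - Y^2))
  prof <- array(0, c(grid$shape, length(chans)))
  for (i in seq_along(chans)) {
    v <- chans[[i]]
    rms <- sqrt(mean(v^2))
    prof[, , , i] <- if (rms > 0) v / rms else v
  }
  coil_profiles(prof, grid, names = names(chans))
}

#' Superpose shim channel fields onto a baseline field
#'
#' `combined = baseline + sum_c currents[c] * profile_c` (the shimmed-field
#' superposition). Affine in the currents; invalid voxels in the baseline or
#' any profile stay invalid.
#'
#' @param baseline a [field_map()].
#' @param profiles a [coil_profiles()] on the same grid.
#' @param currents numeric vector, one value (A) per channel.
#' @return A [field_map()].
#' @export
combine_field <- function(baseline, profiles, currents) {
  stopifnot(inherits(baseline, "field_map"), inherits(profiles, "coil_profiles"))
  if (!grids_equal(baseline$grid, profiles$grid))
    stop("baseline and profiles must share one grid")
  currents <- as.numeric(currents)
  if (length(currents) != profiles$n_channels)
    stop("need one current per channel (", profiles$n_channels, ")")
  active <- which(currents != 0)
  if (!length(active))
    return(field_map(baseline$values, baseline$grid, valid = baseline$valid))
  nvox <- prod(baseline$grid$shape)
  pm <- matrix(profiles$profiles, nrow = nvox)[, active, drop = FALSE]
  add <- as.vector(pm %*% currents[active])
  vals <- as.vector(baseline$values) + add
  field_map(array(vals, baseline$grid$shape), baseline$grid)
}
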
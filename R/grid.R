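#' Regular 3D voxel grid
#'
#' Defines the spatial context shared by field maps, masks, coil profiles and
#' simulated images: an axis-aligned regular grid with a fixed slice axis
#' (the third axis, superior-inferior "z"). Voxel centers sit at
#' `origin + (index - 1) * voxel_size` in millimetres (1-based R indexing;
#' the first voxel center coincides with the origin).
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm positive numeric vector of length 3, voxel edge
#'   lengths in mm.
#' @param origin_mm numeric vector of length 3, physical position (mm) of the
#'   center of the first voxel.
#' @return An object of class `grid3d`.
#' @examples
#' g <- grid3d(c(64, 64, 25), c(2, 2, 5))
#' slice_z(g, 1)
#' @export
grid3d <- function(shape, voxel_size_mm, origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  origin_mm <- as.numeric(origin_mm)
  stopifnot(length(shape) == 3L, length(voxel_size_mm) == 3L,
            length(origin_mm) == 3L)
  if (any(shape < 1L)) stop("all grid dimensions must be >= 1")
  if (any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0))
    stop("all voxel sizes must be positive")
  if (any(!is.finite(origin_mm))) stop("origin must be finite")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 origin_mm = origin_mm),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat("<grid3d> ", paste(x$shape, collapse = " x "),
      " voxels @ ", paste(format(x$voxel_size_mm), collapse = " x "),
      " mm, origin (", paste(format(x$origin_mm), collapse = ", "),
      ") mm\n", sep = "")
  invisible(x)
}

#' Physical coordinates of voxel centers along one axis
#'
#' @param grid a [grid3d()].
#' @param axis integer in 1:3.
#' @return Numeric vector of voxel-center coordinates (mm).
#' @export
axis_coords <- function(grid, axis) {
  stopifnot(inherits(grid, "grid3d"), axis %in% 1:3)
  grid$origin_mm[axis] + (seq_len(grid$shape[axis]) - 1) * grid$voxel_size_mm[axis]
}

#' Physical z coordinate of a slice center
#'
#' @param grid a [grid3d()].
#' @param slice_index 1-based slice index (third axis).
#' @return z coordinate (mm).
#' @export
slice_z <- function(grid, slice_index) {
  stopifnot(all(slice_index >= 1), all(slice_index <= grid$shape[3]))
  grid$origin_mm[3] + (slice_index - 1) * grid$voxel_size_mm[3]
}

#' In-plane voxel-center coordinates of one slice
#'
#' @param grid a [grid3d()].
#' @return Two-column matrix (x_mm, y_mm), one row per in-plane voxel in
#'   column-major (x fastest) order.
#' @export
inplane_coords <- function(grid) {
  x <- axis_coords(grid, 1)
  y <- axis_coords(grid, 2)
  cbind(x_mm = rep(x, times = length(y)), y_mm = rep(y, each = length(x)))
}

grids_equal <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size_mm - b$voxel_size_mm)) <= tol &&
    max(abs(a$origin_mm - b$origin_mm)) <= tol
}

#' Trilinear (or nearest-neighbour) interpolation of a gridded volume
#'
#' Interpolates `values` (an array with dim `grid$shape`) at arbitrary
#' physical points. Points outside the convex hull of voxel centers are
#' flagged invalid (`NA` value), never zero-filled.
#'
#' @param values numeric array, dim equal to `grid$shape`.
#' @param grid a [grid3d()].
#' @param points_mm numeric matrix, n x 3, physical coordinates (mm).
#' @param mode `"trilinear"` or `"nearest"`.
#' @return list with `values` (length n, `NA` where invalid) and `valid`
#'   (logical length n).
#' @keywords internal
#' @export
interp_volume <- function(values, grid, points_mm,
                          mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "grid3d"))
  points_mm <- matrix(as.numeric(points_mm), ncol = 3)
  n <- nrow(points_mm)
  sh <- grid$shape
  # continuous 0-based voxel coordinate
  t1 <- (points_mm[, 1] - grid$origin_mm[1]) / grid$voxel_size_mm[1]
  t2 <- (points_mm[, 2] - grid$origin_mm[2]) / grid$voxel_size_mm[2]
  t3 <- (points_mm[, 3] - grid$origin_mm[3]) / grid$voxel_size_mm[3]
  eps <- 1e-9
  valid <- t1 >= -eps & t1 <= sh[1] - 1 + eps &
           t2 >= -eps & t2 <= sh[2] - 1 + eps &
           t3 >= -eps & t3 <= sh[3] - 1 + eps
  valid[is.na(valid)] <- FALSE
  out <- rep(NA_real_, n)
  if (!any(valid)) return(list(values = out, valid = valid))
  t1 <- pmin(pmax(t1[valid], 0), sh[1] - 1)
  t2 <- pmin(pmax(t2[valid], 0), sh[2] - 1)
  t3 <- pmin(pmax(t3[valid], 0), sh[3] - 1)
  if (mode == "nearest") {
    i <- round(t1) + 1; j <- round(t2) + 1; k <- round(t3) + 1
    out[valid] <- values[cbind(i, j, k)]
    return(list(values = out, valid = valid))
  }
  i0 <- pmin(floor(t1), max(sh[1] - 2, 0)); f1 <- t1 - i0
  j0 <- pmin(floor(t2), max(sh[2] - 2, 0)); f2 <- t2 - j0
  k0 <- pmin(floor(t3), max(sh[3] - 2, 0)); f3 <- t3 - k0
  # degenerate axes (size 1): stay on the single plane
  if (sh[1] == 1L) { i0 <- 0; f1 <- 0 }
  if (sh[2] == 1L) { j0 <- 0; f2 <- 0 }
  if (sh[3] == 1L) { k0 <- 0; f3 <- 0 }
  i1 <- pmin(i0 + 1, sh[1] - 1)
  j1 <- pmin(j0 + 1, sh[2] - 1)
  k1 <- pmin(k0 + 1, sh[3] - 1)
  idx <- function(i, j, k) (i + 1) + j * sh[1] + k * sh[1] * sh[2]
  v <- as.vector(values)
  acc <-
    v[idx(i0, j0, k0)] * (1 - f1) * (1 - f2) * (1 - f3) +
    v[idx(i1, j0, k0)] * f1       * (1 - f2) * (1 - f3) +
    v[idx(i0, j1, k0)] * (1 - f1) * f2       * (1 - f3) +
    v[idx(i1, j1, k0)] * f1       * f2       * (1 - f3) +
    v[idx(i0, j0, k1)] * (1 - f1) * (1 - f2) * f3 +
    v[idx(i1, j0, k1)] * f1       * (1 - f2) * f3 +
    v[idx(i0, j1, k1)] * (1 - f1) * f2       * f3 +
    v[idx(i1, j1, k1)] * f1       * f2       * f3
  out[valid] <- acc
  list(values = out, valid = valid)
}
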
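#' Region-of-interest mask
#'
#' Per-voxel weights in [0, 1] on a [grid3d()]. Binary masks use {0, 1}.
#' `per_slice_count()` gives the number of strictly positive weights per
#' slice - the `N` of the per-slice mean-squared-error objective when the
#' mask is binary.
#'
#' @param weights numeric array with dim equal to `grid$shape`, values in
#'   [0, 1].
#' @param grid a [grid3d()].
#' @return An object of class `shim_mask`.
#' @export
shim_mask <- function(weights, grid) {
  stopifnot(inherits(grid, "grid3d"))
  weights <- array(as.numeric(weights), dim = grid$shape)
  if (any(is.na(weights)) || any(weights < 0) || any(weights > 1))
    stop("mask weights must lie in [0, 1]")
  structure(list(grid = grid, weights = weights), class = "shim_mask")
}

#' @export
print.shim_mask <- function(x, ...) {
  cat("<shim_mask> ", paste(x$grid$shape, collapse = " x "),
      " voxels; ", sum(x$weights > 0), " positive (",
      if (is_binary_mask(x)) "binary" else "soft", ")\n", sep = "")
  invisible(x)
}

is_binary_mask <- function(mask) all(mask$weights %in% c(0, 1))

#' @rdname shim_mask
#' @param mask a `shim_mask`.
#' @export
per_slice_count <- function(mask) {
  stopifnot(inherits(mask, "shim_mask"))
  apply(mask$weights > 0, 3, sum)
}

#' Cylindrical mask centred on the cord centerline
#'
#' Weight 1 where the in-plane physical distance from the slice's centerline
#' point is at most `diameter_mm / 2`, else 0. The cylinder axis is the slice
#' axis; distances are computed in mm, per slice. The two standard pipeline
#' masks are a 40 mm field-map mask and a 25 mm optimization mask on the same
#' centerline (the smaller is always contained in the larger).
#'
#' @param centerline numeric nz x 2 matrix of per-slice (x, y) centerline
#'   coordinates in mm (one row per slice of `grid`).
#' @param diameter_mm cylinder diameter (mm); must be at least one in-plane
#'   voxel, otherwise slices could be empty and the per-slice objective
#'   undefined.
#' @param grid a [grid3d()].
#' @return A binary [shim_mask()].
#' @export
cylindrical_mask <- function(centerline, diameter_mm, grid) {
  stopifnot(inherits(grid, "grid3d"))
  centerline <- matrix(as.numeric(centerline), ncol = 2)
  if (nrow(centerline) != grid$shape[3])
    stop("centerline must have one (x, y) row per slice")
  if (!(diameter_mm >= min(grid$voxel_size_mm[1:2])))
    stop("diameter smaller than one in-plane voxel would give empty slices")
  xy <- inplane_coords(grid)
  nxy <- nrow(xy)
  w <- array(0, grid$shape)
  r <- diameter_mm / 2
  for (s in seq_len(grid$shape[3])) {
    d2 <- (xy[, 1] - centerline[s, 1])^2 + (xy[, 2] - centerline[s, 2])^2
    w[, , s] <- as.numeric(d2 <= r^2)
  }
  shim_mask(w, grid)
}

#' Gaussian-tapered soft mask
#'
#' Keeps weight 1 inside the binary region and decays outside as
#' `exp(-d^2 / (2 sigma_mm^2))` of the in-plane distance `d` to the region
#' (distance to the nearest positive voxel center, per slice), truncated to 0
#' below `floor`.
#'
#' @param binary a binary [shim_mask()].
#' @param sigma_mm Gaussian decay length (mm, > 0).
#' @param floor weights below this value are set to 0 (default 0.01).
#' @return A soft [shim_mask()].
#' @export
soft_mask <- function(binary, sigma_mm, floor = 0.01) {
  stopifnot(inherits(binary, "shim_mask"), sigma_mm > 0)
  if (!is_binary_mask(binary)) stop("input mask must be binary")
  g <- binary$grid
  xy <- inplane_coords(g)
  w <- binary$weights
  out <- array(0, g$shape)
  for (s in seq_len(g$shape[3])) {
    ws <- as.vector(w[, , s])
    inside <- ws > 0
    res <- ws
    if (any(inside) && !all(inside)) {
      pin <- xy[inside, , drop = FALSE]
      pout <- xy[!inside, , drop = FALSE]
      # min squared distance from each outside voxel to the region
      d2 <- outer(pout[, 1], pin[, 1], "-")^2 +
            outer(pout[, 2], pin[, 2], "-")^2
      dmin2 <- apply(d2, 1, min)
      val <- exp(-dmin2 / (2 * sigma_mm^2))
      val[val < floor] <- 0
      res[!inside] <- val
    }
    out[, , s] <- res
  }
  shim_mask(out, g)
}

#' Resample a mask onto another grid
#'
#' Trilinearly resamples the weights; binary masks are re-binarized at
#' `threshold` (default 0.5), soft masks stay continuous. Voxels outside the
#' source extent get weight 0. If any slice that had positive weights in the
#' source comes out empty, the result carries an `empty_slices` attribute
#' naming them.
#'
#' @param mask a [shim_mask()].
#' @param target a [grid3d()].
#' @param threshold binarization threshold in [0, 1] applied when the source
#'   is binary (weight kept when interpolated value >= threshold).
#' @return A [shim_mask()] on `target`.
#' @export
mask_to_grid <- function(mask, target, threshold = 0.5) {
  stopifnot(inherits(mask, "shim_mask"), inherits(target, "grid3d"),
            threshold >= 0, threshold <= 1)
  binary <- is_binary_mask(mask)
  pts <- grid_centers(target)
  res <- interp_volume(mask$weights, mask$grid, pts, mode = "trilinear")
  w <- res$values
  w[!res$valid] <- 0
  if (binary) w <- as.numeric(w >= threshold)
  w <- pmin(pmax(w, 0), 1)
  out <- shim_mask(array(w, target$shape), target)
  counts <- per_slice_count(out)
  empty <- which(counts == 0)
  if (length(empty)) attr(out, "empty_slices") <- empty
  out
}
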
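grid_affine <- function(grid) {
  aff <- diag(c(grid$voxel_size_mm, 1))
  aff[1:3, 4] <- grid$origin_mm
  aff
}

as_nifti_volume <- function(values, grid) {
  img <- RNifti::asNifti(values)
  aff <- structure(grid_affine(grid), code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  img
}

grid_from_nifti <- function(img) {
  d <- dim(img)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  if (max(abs(aff[1:3, 1:3] - diag(diag(aff[1:3, 1:3])))) > 1e-6)
    stop("only axis-aligned NIfTI volumes are supported")
  grid3d(d[1:3], diag(aff[1:3, 1:3]), aff[1:3, 4])
}

#' Read and write fields, masks and coil profiles as NIfTI
#'
#' Fields and soft masks are written as float32, binary masks as uint8, label
#' maps as int16, coil profile sets as 4D volumes (x, y, z, channel) with a
#' JSON sidecar carrying channel names. The grid affine is stored in the
#' sform/qform (axis-aligned only).
#'
#' @param field a [field_map()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return Readers return the corresponding package object; writers return
#'   `path` invisibly.
#' @name shim_nifti
#' @export
write_field_nifti <- function(field, path) {
  stopifnot(inherits(field, "field_map"))
  vals <- field$values
  img <- as_nifti_volume(vals, field$grid)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname shim_nifti
#' @export
read_field_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  field_map(array(as.numeric(img), dim(img)[1:3]), grid_from_nifti(img))
}

#' @rdname shim_nifti
#' @param mask a [shim_mask()].
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "shim_mask"))
  dt <- if (is_binary_mask(mask)) "uint8" else "float"
  img <- as_nifti_volume(mask$weights, mask$grid)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' @rdname shim_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  shim_mask(array(as.numeric(img), dim(img)[1:3]), grid_from_nifti(img))
}

#' @rdname shim_nifti
#' @param profiles a [coil_profiles()].
#' @export
write_coil_nifti <- function(profiles, path) {
  stopifnot(inherits(profiles, "coil_profiles"))
  img <- as_nifti_volume(profiles$profiles, profiles$grid)
  RNifti::writeNifti(img, path, datatype = "float")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(channel_names = profiles$names), side,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname shim_nifti
#' @export
read_coil_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stopifnot(length(d) == 4L)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  nms <- NULL
  if (file.exists(side))
    nms <- unlist(jsonlite::read_json(side)$channel_names)
  coil_profiles(array(as.numeric(img), d), grid_from_nifti(img), names = nms)
}

#' Read and write a cord centerline as JSON
#'
#' Format: an object mapping 1-based slice indices to `[x_mm, y_mm]` pairs,
#' e.g. `{"1": [64.0, 58.5], ...}`. This is the hand-off point for an
#' externally segmented centerline; image-based cord segmentation is out of
#' scope.
#'
#' @param centerline nz x 2 matrix of (x, y) mm.
#' @param path file path.
#' @return `read_centerline_json()` returns the nz x 2 matrix.
#' @export
write_centerline_json <- function(centerline, path) {
  centerline <- matrix(as.numeric(centerline), ncol = 2)
  obj <- stats::setNames(
    lapply(seq_len(nrow(centerline)), function(s) unname(centerline[s, ])),
    as.character(seq_len(nrow(centerline))))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_centerline_json
#' @export
read_centerline_json <- function(path) {
  obj <- jsonlite::read_json(path)
  idx <- as.integer(names(obj))
  out <- matrix(NA_real_, max(idx), 2)
  for (i in seq_along(obj)) out[idx[i], ] <- unlist(obj[[i]])
  colnames(out) <- c("x_mm", "y_mm")
  out
}

#' Write a shim solution for a current controller
#'
#' One row per slice: slice index, per-channel currents (A), the objective
#' terms, and the solver status - the shape a shim-amplifier controller
#' consumes. JSON (structured) and CSV (flat) are supported, chosen by the
#' file extension.
#'
#' @param fit a [shim_fit()].
#' @param path output path ending in `.json` or `.csv`.
#' @export
write_shim_solution <- function(fit, path) {
  stopifnot(inherits(fit, "shim_fit"))
  df <- data.frame(slice_index = fit$slices, fit$currents,
                   mse_term = fit$objective$mse_term,
                   grad_term = fit$objective$grad_term,
                   status = fit$objective$status,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(method = fit$method, w = fit$w,
           channel_bound_A = fit$control$channel_bound_A,
           total_bound_A = fit$control$total_bound_A,
           channels = fit$channel_names, solution = df),
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (grepl("\\.csv$", path)) {
    utils::write.csv(df, path, row.names = FALSE)
  } else stop("path must end in .json or .csv")
  invisible(path)
}

#' @rdname write_shim_solution
#' @return `read_shim_solution()` returns a list with `currents` (matrix),
#'   `slices`, `w`, `method` and the per-slice `status`.
#' @export
read_shim_solution <- function(path) {
  stopifnot(grepl("\\.json$", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ch <- unlist(obj$channels)
  sol <- obj$solution
  currents <- as.matrix(sol[, ch, drop = FALSE])
  rownames(currents) <- sol$slice_index
  list(currents = currents, slices = as.integer(sol$slice_index),
       w = obj$w, method = obj$method, status = sol$status)
}

#' Write the phantom sidecar (spec, echo times, level table)
#'
#' @param phantom a `spinal_phantom`.
#' @param path JSON path.
#' @param te_s optional echo times (s) recorded alongside.
#' @export
write_phantom_sidecar <- function(phantom, path, te_s = c(0.00268, 0.00492)) {
  sp <- phantom$spec
  jsonlite::write_json(
    list(grid = list(shape = sp$grid$shape,
                     voxel_size_mm = sp$grid$voxel_size_mm,
                     origin_mm = sp$grid$origin_mm),
         cord_radius_mm = sp$cord_radius_mm,
         centerline_amplitude_mm = sp$centerline_amplitude_mm,
         disc_period_mm = sp$disc_period_mm,
         disc_amplitude_hz = sp$disc_amplitude_hz,
         disc_offset_mm = sp$disc_offset_mm,
         disc_sigma_mm = sp$disc_sigma_mm,
         caudal_gradient_hz_per_mm = sp$caudal_gradient_hz_per_mm,
         caudal_start_slice = sp$caudal_start_slice,
         background_poly_coeffs = as.list(sp$background_poly_coeffs),
         noise_sigma = sp$noise_sigma, seed = sp$seed,
         echo_times_s = te_s,
         level_table = phantom$level_table),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
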
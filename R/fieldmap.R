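#' Off-resonance field map
#'
#' A scalar off-resonance field on a [grid3d()], in Hz (f = gamma * dB0 / 2pi).
#' All fields in this package are carried in Hz; conversion to rad/s happens
#' only inside the signal model. Voxels may be flagged invalid (no signal,
#' outside the source extent after resampling, ...); invalid voxels hold `NA`
#' and are excluded from optimization and metrics - invalid is never zero,
#' because 0 Hz is a meaningful field value.
#'
#' @param values numeric array with dim equal to `grid$shape`; `NA` marks
#'   invalid voxels.
#' @param grid a [grid3d()].
#' @param valid optional logical array (same dim); defaults to `!is.na(values)`.
#' @return An object of class `field_map` with elements `grid`, `values`,
#'   `valid`.
#' @export
field_map <- function(values, grid, valid = NULL) {
  stopifnot(inherits(grid, "grid3d"))
  values <- array(as.numeric(values), dim = grid$shape)
  if (is.null(valid)) valid <- !is.na(values)
  valid <- array(as.logical(valid), dim = grid$shape)
  values[!valid] <- NA_real_
  if (any(!is.finite(values[valid])))
    stop("field values must be finite inside the valid mask")
  structure(list(grid = grid, values = values, valid = valid),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat("<field_map> ", paste(x$grid$shape, collapse = " x "),
      " voxels, ", sum(x$valid), " valid; range [",
      if (length(v)) paste(format(range(v), digits = 4), collapse = ", ") else "",
      "] Hz\n", sep = "")
  invisible(x)
}

#' Estimate a B0 field map from dual-echo complex GRE data
#'
#' Computes the per-voxel off-resonance frequency from the phase of the
#' complex conjugate product of the two echoes:
#' `f = Arg(Conj(echo1) * echo2) / (2 * pi * dTE)`, with the argument in
#' (-pi, pi]. The conjugate product avoids per-echo phase-wrap artifacts.
#' No spatial unwrapping is performed, so the unambiguous range is
#' `+/- 1 / (2 * dTE)` (about +/-223 Hz for the default field-map echo times
#' 2.68 / 4.92 ms); frequencies beyond it alias back into that interval.
#'
#' @param echo1,echo2 complex arrays on a common grid, or `echo1` may be a
#'   `dual_echo` object from [simulate_dual_echo()] (then the remaining
#'   arguments are taken from it).
#' @param te1_s,te2_s echo times in seconds, `te2_s > te1_s > 0`.
#' @param grid the [grid3d()] of the echoes.
#' @return A [field_map()]; voxels where either echo has zero magnitude are
#'   flagged invalid.
#' @examples
#' g <- grid3d(c(4, 4, 3), c(2, 2, 5))
#' f0 <- field_map(array(100, g$shape), g)
#' de <- simulate_dual_echo(f0, 0.00268, 0.00492)
#' fm <- phase_difference_fieldmap(de)
#' range(fm$values)  # 100 Hz recovered
#' @export
phase_difference_fieldmap <- function(echo1, echo2 = NULL, te1_s = NULL,
                                      te2_s = NULL, grid = NULL) {
  if (inherits(echo1, "dual_echo")) {
    de <- echo1
    echo1 <- de$echo1; echo2 <- de$echo2
    te1_s <- de$te1_s; te2_s <- de$te2_s; grid <- de$grid
  }
  stopifnot(inherits(grid, "grid3d"), is.complex(echo1), is.complex(echo2))
  if (!identical(dim(echo1), dim(echo2)) ||
      !identical(as.integer(dim(echo1)), grid$shape))
    stop("echoes must share the grid's dimensions")
  if (!(te2_s > te1_s && te1_s > 0))
    stop("echo times must satisfy te2_s > te1_s > 0")
  dte <- te2_s - te1_s
  prod <- Conj(echo1) * echo2
  f <- Arg(prod) / (2 * pi * dte)
  valid <- Mod(echo1) > 0 & Mod(echo2) > 0
  f[!valid] <- NA_real_
  field_map(array(f, grid$shape), grid, valid = array(valid, grid$shape))
}

#' Resample a field map onto another grid
#'
#' Interpolates at the target voxel centers. Target voxels outside the
#' source's physical extent - and, for trilinear mode, voxels whose
#' interpolation stencil touches an invalid source voxel - are flagged
#' invalid.
#'
#' @param field a [field_map()].
#' @param target a [grid3d()]; must overlap the source extent.
#' @param mode `"trilinear"` (default) or `"nearest"`.
#' @return A [field_map()] on `target`.
#' @export
resample_field <- function(field, target, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(field, "field_map"), inherits(target, "grid3d"))
  pts <- grid_centers(target)
  vals <- field$values
  vals_filled <- vals
  vals_filled[is.na(vals_filled)] <- 0
  res <- interp_volume(vals_filled, field$grid, pts, mode = mode)
  ok <- res$valid
  if (!any(ok)) stop("target grid does not overlap the source extent")
  if (any(!field$valid)) {
    vres <- interp_volume(array(as.numeric(field$valid), field$grid$shape),
                          field$grid, pts, mode = mode)
    ok <- ok & !is.na(vres$values) & vres$values > 1 - 1e-9
  }
  out <- res$values
  out[!ok] <- NA_real_
  field_map(array(out, target$shape), target,
            valid = array(ok, target$shape))
}

# all voxel centers of a grid as an n x 3 matrix (x fastest)
grid_centers <- function(grid) {
  x <- axis_coords(grid, 1); y <- axis_coords(grid, 2); z <- axis_coords(grid, 3)
  nx <- length(x); ny <- length(y); nz <- length(z)
  cbind(rep(x, times = ny * nz),
        rep(rep(y, each = nx), times = nz),
        rep(z, each = nx * ny))
}
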
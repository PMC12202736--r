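#' Per-slice in-plane B0 RMSE
#'
#' Square root of the weighted mean of the squared field over the masked
#' voxels of one slice (Hz): the standard in-plane homogeneity metric of a
#' residual (shimmed) field. Invalid field voxels are excluded.
#'
#' @param field a [field_map()].
#' @param mask a [shim_mask()] on the same grid.
#' @param slice_index 1-based slice index (needs >= 1 masked voxel).
#' @return RMSE in Hz.
#' @examples
#' g <- grid3d(c(2, 1, 3), c(1, 1, 1))
#' f <- field_map(array(c(3, 4), g$shape), g)
#' m <- shim_mask(array(1, g$shape), g)
#' slice_rmse(f, m, 1)  # sqrt(12.5)
#' @export
slice_rmse <- function(field, mask, slice_index) {
  stopifnot(inherits(field, "field_map"), inherits(mask, "shim_mask"))
  if (!grids_equal(field$grid, mask$grid))
    stop("field and mask must share one grid")
  s <- as.integer(slice_index)
  stopifnot(s >= 1, s <= field$grid$shape[3])
  w <- mask$weights[, , s]
  f <- field$values[, , s]
  use <- w > 0 & !is.na(f)
  if (!any(use)) stop("no masked valid voxels on slice ", s)
  sqrt(sum(w[use] * f[use]^2) / sum(w[use]))
}

#' Voxel-wise temporal SNR map
#'
#' Temporal mean divided by temporal standard deviation (sample SD, n - 1)
#' per masked voxel of a simulated or acquired EPI time series. Voxels with
#' zero temporal SD are undefined (`NA`) and excluded from aggregates, as are
#' voxels outside the mask.
#'
#' @param ts an `epi_series` (see [simulate_epi()]) or a 4D array.
#' @param mask a [shim_mask()]; default: all voxels.
#' @return nx x ny x nz array of tSNR values (`NA` where undefined).
#' @export
tsnr_map <- function(ts, mask = NULL) {
  if (inherits(ts, "epi_series")) {
    data <- ts$data
    if (is.null(mask)) mask <- shim_mask(array(1, ts$grid$shape), ts$grid)
    if (!grids_equal(ts$grid, mask$grid))
      stop("time series and mask must share one grid")
  } else {
    data <- ts
    stopifnot(length(dim(data)) == 4L)
  }
  nv <- dim(data)[4]
  if (nv < 2) stop("need at least 2 volumes for a temporal SD")
  mu <- apply(data, 1:3, mean)
  sd <- apply(data, 1:3, stats::sd)
  out <- mu / sd
  out[sd == 0] <- NA_real_
  if (!is.null(mask)) out[mask$weights <= 0] <- NA_real_
  out
}

#' Mean per-slice value of a voxel map
#'
#' Convenience aggregator: the mean of defined (non-`NA`) voxel values per
#' slice, e.g. of a [tsnr_map()].
#'
#' @param map nx x ny x nz array.
#' @param slices slice indices (default all).
#' @return Named numeric vector, one value per slice (`NA` if no defined
#'   voxel).
#' @export
per_slice_mean <- function(map, slices = NULL) {
  d <- dim(map)
  stopifnot(length(d) == 3L)
  if (is.null(slices)) slices <- seq_len(d[3])
  out <- vapply(slices, function(s) {
    v <- map[, , s]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  names(out) <- slices
  out
}

#' Aggregate per-slice values by vertebral level
#'
#' @param per_slice_values numeric vector of per-slice values whose names (or
#'   positions, if unnamed) are 1-based slice indices; `NA` entries are
#'   dropped.
#' @param level_table data frame with columns `level`, `first_slice`,
#'   `last_slice` (see [default_level_table()]); every slice carrying a value
#'   must fall in exactly one level.
#' @return Data frame with one row per level present: `level`, `mean`, `sd`
#'   (sample SD; `NA` for single-slice levels is reported as 0), `n_slices`.
#' @export
aggregate_by_level <- function(per_slice_values, level_table) {
  stopifnot(is.data.frame(level_table),
            all(c("level", "first_slice", "last_slice") %in% names(level_table)))
  v <- per_slice_values[!is.na(per_slice_values)]
  idx <- if (!is.null(names(v))) as.integer(names(v)) else seq_along(v)
  hits <- vapply(idx, function(s)
    sum(s >= level_table$first_slice & s <= level_table$last_slice),
    integer(1))
  if (any(hits != 1L))
    stop("slice(s) not assigned to exactly one level: ",
         paste(idx[hits != 1L], collapse = ", "))
  lev <- vapply(idx, function(s)
    which(s >= level_table$first_slice & s <= level_table$last_slice),
    integer(1))
  rows <- sort(unique(lev))
  data.frame(
    level = level_table$level[rows],
    mean = vapply(rows, function(r) mean(v[lev == r]), numeric(1)),
    sd = vapply(rows, function(r) {
      x <- v[lev == r]
      if (length(x) < 2) 0 else stats::sd(x)
    }, numeric(1)),
    n_slices = vapply(rows, function(r) sum(lev == r), integer(1)),
    stringsAsFactors = FALSE)
}

#' Percent improvement relative to a reference
#'
#' `100 * (value - reference) / reference`; the form used to report, e.g.,
#' tSNR improvement of a shimmed acquisition over its baseline.
#'
#' @param value numeric (vectorized).
#' @param reference positive reference value(s).
#' @return Percent improvement (negative = worse than reference).
#' @export
percent_improvement <- function(value, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("reference must be > 0")
  100 * (value - reference) / reference
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two samples, as used to compare per-slice B0 RMSE
#' distributions between shim conditions. The U statistic uses midranks for
#' ties. The p-value is exact (enumeration) when both samples are free of
#' ties and `min(n_x, n_y) <= 8`, and otherwise uses the normal approximation
#' with tie and continuity corrections. Computation is delegated to
#' [stats::wilcox.test()], whose W statistic equals U for this orientation.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `U`, `p_two_sided`, and `method` ("exact" or
#'   "normal_approx").
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= 8
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = U, p_two_sided = unname(ht$p.value),
       method = if (exact) "exact" else "normal_approx")
}
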
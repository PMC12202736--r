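#' @export
print.shim_fit <- function(x, ...) {
  cat("Shim fit (", if (x$method == "dynamic") "dynamic slice-wise"
      else "volume-wise", ")\n", sep = "")
  cat("  channels: ", length(x$channel_names), ", slices: ",
      length(x$slices), ", w = ", format(x$w), "\n", sep = "")
  cat("  mean |I| per slice: ",
      format(mean(rowSums(abs(x$currents))), digits = 4), " A (bound ",
      format(x$control$total_bound_A), " A)\n", sep = "")
  ok <- x$objective$status == "ok"
  if (!all(ok))
    cat("  ", sum(!ok), " slice(s) fell back to zero currents\n", sep = "")
  invisible(x)
}

#' @export
summary.shim_fit <- function(object, ...) {
  obj <- object$objective
  rmse <- sqrt(obj$mse_term)
  rmse0 <- sqrt(obj$mse_zero)
  out <- list(
    method = object$method, w = object$w,
    n_channels = length(object$channel_names),
    slices = object$slices,
    per_slice = data.frame(
      slice = obj$slice,
      rmse_hz = rmse, rmse_unshimmed_hz = rmse0,
      grad_term = obj$grad_term, grad_unshimmed = obj$grad_zero,
      sum_abs_current_A = rowSums(abs(object$currents)),
      max_abs_current_A = apply(abs(object$currents), 1, max),
      status = obj$status),
    mean_rmse_hz = mean(rmse),
    mean_rmse_unshimmed_hz = mean(rmse0),
    rmse_reduction_pct = 100 * (1 - mean(rmse) / mean(rmse0)),
    constraints_ok = all(abs(object$currents) <=
                           object$control$channel_bound_A + 1e-6) &&
      all(rowSums(abs(object$currents)) <=
            object$control$total_bound_A + 1e-6))
  class(out) <- "summary.shim_fit"
  out
}

#' @export
print.summary.shim_fit <- function(x, ...) {
  cat("Shim fit summary (", x$method, ", w = ", format(x$w), ")\n", sep = "")
  cat("  slices: ", length(x$slices), ", channels: ", x$n_channels, "\n",
      sep = "")
  cat("  mean in-mask RMSE: ", format(x$mean_rmse_hz, digits = 4),
      " Hz (unshimmed ", format(x$mean_rmse_unshimmed_hz, digits = 4),
      " Hz, reduction ", format(x$rmse_reduction_pct, digits = 3),
      "%)\n", sep = "")
  cat("  constraints satisfied: ", x$constraints_ok, "\n", sep = "")
  print(utils::head(x$per_slice, 10))
  if (nrow(x$per_slice) > 10)
    cat("  ... (", nrow(x$per_slice) - 10, " more slices)\n", sep = "")
  invisible(x)
}

#' @export
coef.shim_fit <- function(object, ...) object$currents

# field actually realised slice by slice: plane s of the output carries
# baseline + coil field at slice s's currents (other planes: baseline)
effective_field <- function(fit) {
  g <- fit$baseline$grid
  vals <- fit$baseline$values
  nvox_plane <- g$shape[1] * g$shape[2]
  pm <- matrix(fit$profiles$profiles, nrow = prod(g$shape))
  for (i in seq_along(fit$slices)) {
    s <- fit$slices[i]
    I <- fit$currents[i, ]
    active <- which(I != 0)
    if (!length(active)) next
    rows <- (s - 1) * nvox_plane + seq_len(nvox_plane)
    add <- pm[rows, active, drop = FALSE] %*% I[active]
    vals[, , s] <- vals[, , s] + array(add, g$shape[1:2])
  }
  field_map(vals, g)
}

#' @export
fitted.shim_fit <- function(object, ...) effective_field(object)

#' Residual off-resonance field of a shim fit
#'
#' The shimmed field is itself the residual (the target is 0 Hz everywhere in
#' the ROI). Returns the effective per-slice shimmed field restricted to the
#' optimization mask; voxels outside the mask are invalid.
#'
#' @param object a [shim_fit()].
#' @param ... unused.
#' @return A [field_map()].
#' @export
residuals.shim_fit <- function(object, ...) {
  eff <- effective_field(object)
  keep <- object$mask$weights > 0 & eff$valid
  vals <- eff$values
  vals[!keep] <- NA_real_
  field_map(vals, eff$grid, valid = keep)
}

#' Predictions from a shim fit
#'
#' @param object a [shim_fit()].
#' @param type `"field"` for the effective per-slice shimmed field,
#'   `"loss"` for the predicted signal-loss map (each slice evaluated under
#'   its own currents applied to the whole volume, so the through-slice
#'   stencil sees the true field of that excitation), or `"rmse"` for the
#'   per-slice in-mask B0 RMSE (Hz).
#' @param acq an [acq_params()] (used for `type = "loss"`).
#' @param slices slice subset (default: the fitted slices).
#' @param ... unused.
#' @return A [field_map()], `signal_loss_map`, or named numeric vector.
#' @export
predict.shim_fit <- function(object, type = c("field", "loss", "rmse"),
                             acq = acq_params(), slices = NULL, ...) {
  type <- match.arg(type)
  if (is.null(slices)) slices <- object$slices
  slices <- as.integer(slices)
  if (type == "field") return(effective_field(object))
  if (type == "rmse") {
    eff <- effective_field(object)
    out <- vapply(slices, function(s) slice_rmse(eff, object$mask, s),
                  numeric(1))
    names(out) <- slices
    return(out)
  }
  g <- object$baseline$grid
  L <- array(NA_real_, g$shape)
  PHI <- array(NA_real_, g$shape)
  for (s in slices) {
    i <- match(s, object$slices)
    I <- if (!is.na(i)) object$currents[i, ] else rep(0, ncol(object$currents))
    fld <- combine_field(object$baseline, object$profiles, I)
    gr <- through_slice_gradient(fld, s, acq$slice_thickness_mm)
    phi <- phase_dispersion(gr, acq$slice_thickness_mm, acq$te_s)
    PHI[, , s] <- phi
    L[, , s] <- signal_loss(phi)
  }
  structure(list(grid = g, L = L, phi = PHI, slices = slices),
            class = "signal_loss_map")
}

#' Simulate EPI data under a fitted shim
#'
#' Runs [simulate_epi()] with the fit's effective per-slice field: the
#' phase-encode displacement of slice s uses the in-plane field at slice s's
#' currents, and the through-slice attenuation uses the gradient of the full
#' field generated by those currents.
#'
#' @param object a [shim_fit()].
#' @param nsim number of volumes (defaults to `acq$n_volumes`).
#' @param seed noise seed (defaults to `acq$seed`).
#' @param labelmap integer tissue label map (0/1/2), e.g. from
#'   [make_phantom()].
#' @param acq an [acq_params()].
#' @param ... unused.
#' @return An `epi_series`.
#' @export
simulate.shim_fit <- function(object, nsim = NULL, seed = NULL,
                              labelmap = NULL, acq = acq_params(), ...) {
  if (is.null(labelmap))
    stop("a labelmap (tissue template) is required to simulate EPI data")
  if (!is.null(nsim)) acq$n_volumes <- as.integer(nsim)
  if (!is.null(seed)) acq$seed <- as.integer(seed)
  g <- object$baseline$grid
  gmap <- array(NA_real_, g$shape)
  for (s in seq_len(g$shape[3])) {
    i <- match(s, object$slices)
    I <- if (!is.na(i)) object$currents[i, ] else rep(0, ncol(object$currents))
    fld <- combine_field(object$baseline, object$profiles, I)
    gmap[, , s] <- through_slice_gradient(fld, s, acq$slice_thickness_mm)
  }
  simulate_epi(labelmap, effective_field(object), acq, gmap = gmap)
}

#' Diagnostic plot of a shim fit
#'
#' Two panels: per-slice in-mask RMSE before/after shimming, and the
#' per-slice currents.
#'
#' @param x a [shim_fit()].
#' @param ... passed to [graphics::matplot()] for the currents panel.
#' @export
plot.shim_fit <- function(x, ...) {
  obj <- x$objective
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(obj$slice, sqrt(obj$mse_zero), type = "b", pch = 1,
                 xlab = "slice (caudal to rostral)", ylab = "in-mask RMSE (Hz)",
                 main = "B0 homogeneity",
                 ylim = range(0, sqrt(obj$mse_zero), sqrt(obj$mse_term)))
  graphics::lines(obj$slice, sqrt(obj$mse_term), type = "b", pch = 16,
                  col = "firebrick")
  graphics::legend("topright", legend = c("unshimmed", "shimmed"),
                   pch = c(1, 16), col = c("black", "firebrick"), bty = "n")
  graphics::matplot(obj$slice, x$currents, type = "l", lty = 1,
                    xlab = "slice (caudal to rostral)", ylab = "current (A)",
                    main = paste0("channel currents (w = ", format(x$w), ")"),
                    ...)
  graphics::abline(h = c(-1, 1) * x$control$channel_bound_A, lty = 3)
  invisible(x)
}
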
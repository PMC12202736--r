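#' Acquisition parameters for the GRE-EPI simulator
#'
#' Defaults follow a typical axial spinal-cord fMRI protocol: TE = 32 ms,
#' 5 mm slices, TR = 2.07 s, 60 volumes. `total_readout_time_s` is the
#' per-phase-encode-line time constant of the adopted distortion convention
#' (see [simulate_epi()]); the default 5e-4 s shifts a 30 Hz off-resonance
#' voxel by about one voxel on a 64-line acquisition.
#'
#' @param te_s echo time (s), must be < `tr_s`.
#' @param slice_thickness_mm slice thickness Delta-z (mm).
#' @param tr_s repetition time (s).
#' @param n_volumes number of repeated volumes (>= 1).
#' @param pe_axis in-plane phase-encode axis: 1 (x) or 2 (y, the
#'   anterior-posterior default).
#' @param total_readout_time_s positive readout-time constant (s).
#' @param noise_sigma complex Gaussian noise SD per component (image units).
#' @param seed integer seed for the noise stream.
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(te_s = 0.032, slice_thickness_mm = 5, tr_s = 2.07,
                       n_volumes = 60L, pe_axis = 2L,
                       total_readout_time_s = 5e-4, noise_sigma = 0.05,
                       seed = 1L) {
  stopifnot(te_s > 0, tr_s > 0, te_s < tr_s, slice_thickness_mm > 0,
            n_volumes >= 1, pe_axis %in% 1:2, noise_sigma >= 0)
  if (total_readout_time_s <= 0) stop("total_readout_time_s must be > 0")
  structure(list(te_s = te_s, slice_thickness_mm = slice_thickness_mm,
                 tr_s = tr_s, n_volumes = as.integer(n_volumes),
                 pe_axis = as.integer(pe_axis),
                 total_readout_time_s = total_readout_time_s,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "acq_params")
}

#' Phase dispersion across a slice
#'
#' `phi = 2 pi * g * Delta-z * TE` (radians): the total phase spread across a
#' slice of thickness Delta-z under a linear through-slice gradient `g`
#' expressed in Hz/mm. (With the field carried in Hz the gyromagnetic ratio
#' is already absorbed; the 2 pi converts cycles to radians.) Linear in each
#' argument.
#'
#' @param g_hz_per_mm through-slice gradient (Hz/mm); vectorized.
#' @param delta_z_mm slice thickness (mm, > 0).
#' @param te_s echo time (s, > 0).
#' @return Phase dispersion in radians.
#' @examples
#' phase_dispersion(1, 5, 0.032)  # 2*pi*0.16
#' @export
phase_dispersion <- function(g_hz_per_mm, delta_z_mm, te_s) {
  stopifnot(delta_z_mm > 0, te_s > 0)
  2 * pi * g_hz_per_mm * delta_z_mm * te_s
}

#' Fractional signal loss from through-slice dephasing
#'
#' `L = 1 - sinc(phi / 2)` with the *unnormalized* sinc
#' (`sin(x) / x`, `sinc(0) = 1`): the magnitude attenuation of a rectangular
#' slice profile with uniform spin density and a linear field variation
#' through the slice. Even in `phi`; `L(0) = 0`, `L(2 pi) = 1`, and the
#' global maximum `1 - min(sinc) = 1.2172` is reached near `phi = 8.986`.
#'
#' @param phi phase dispersion (radians); vectorized.
#' @return Signal loss `L` (dimensionless, signed as `1 - sinc`).
#' @examples
#' signal_loss(pi)  # 1 - 2/pi
#' @export
signal_loss <- function(phi) {
  1 - sinc_unnorm(phi / 2)
}

sinc_unnorm <- function(x) {
  out <- x
  small <- !is.na(x) & abs(x) < 1e-6
  big <- !is.na(x) & !small
  out[big] <- sin(x[big]) / x[big]
  out[small] <- 1 - x[small]^2 / 6
  out
}

#' Predicted signal-loss map of a field
#'
#' Per voxel of each listed slice: the through-slice gradient of the field
#' ([through_slice_gradient()] with stencil width = slice thickness), the
#' phase dispersion from [phase_dispersion()], and the loss from
#' [signal_loss()]. Works on a baseline or a shimmed (combined) field; for a
#' fitted dynamic shim use `predict(fit, type = "loss")`, which applies each
#' slice's own currents.
#'
#' @param field a [field_map()].
#' @param acq an [acq_params()] (TE and slice thickness are used).
#' @param slices slice indices (default all).
#' @return An object of class `signal_loss_map`: list with `grid`, `L` and
#'   `phi` arrays (`NA` on slices not requested), `slices`.
#' @export
predict_signal_loss <- function(field, acq = acq_params(), slices = NULL) {
  stopifnot(inherits(field, "field_map"), inherits(acq, "acq_params"))
  g <- field$grid
  if (is.null(slices)) slices <- seq_len(g$shape[3])
  L <- array(NA_real_, g$shape)
  PHI <- array(NA_real_, g$shape)
  for (s in slices) {
    gr <- through_slice_gradient(field, s, acq$slice_thickness_mm)
    phi <- phase_dispersion(gr, acq$slice_thickness_mm, acq$te_s)
    PHI[, , s] <- phi
    L[, , s] <- signal_loss(phi)
  }
  structure(list(grid = g, L = L, phi = PHI, slices = as.integer(slices)),
            class = "signal_loss_map")
}

#' @export
print.signal_loss_map <- function(x, ...) {
  v <- x$L[!is.na(x$L)]
  cat("<signal_loss_map> ", length(x$slices), " slices; mean L = ",
      format(mean(v), digits = 4), ", max L = ",
      format(max(v), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Simulate a GRE-EPI magnitude time series
#'
#' A deliberately simple forward model for temporal-SNR experiments:
#' \enumerate{
#'   \item tissue template from the label map (cord 1.0, other body tissue
#'     0.4, background 0);
#'   \item through-slice dephasing attenuation `|sinc(phi/2)|` per voxel
#'     (phase dispersion from the slice's through-slice gradient; magnitude
#'     images cannot go negative, hence the absolute value);
#'   \item off-resonance displacement along the phase-encode axis of
#'     `f_hz * total_readout_time_s * N_pe` voxels (linear interpolation, no
#'     intensity correction);
#'   \item per volume, Rician magnitude noise: `|m + sigma (e1 + i e2)|`
#'     with fresh seeded complex Gaussian noise each volume.
#' }
#' No T2* decay, physiological fluctuation, in-plane dephasing or k-space
#' effects are modelled.
#'
#' @param labelmap integer array (0 background / 1 body / 2 cord), e.g. from
#'   [make_phantom()].
#' @param field a [field_map()] on the same grid (the field seen by the
#'   acquisition; for dynamic shimming pass per-slice gradients via `gmap`).
#' @param acq an [acq_params()].
#' @param gmap optional nx x ny x nz array of through-slice gradients
#'   (Hz/mm) overriding those derived from `field` (used by
#'   `simulate.shim_fit()`, where the attenuation of slice s must come from
#'   the full field produced by slice s's own currents).
#' @return An object of class `epi_series`: list with `grid`, `data`
#'   (nx x ny x nz x n_volumes array) and `acq`.
#' @export
simulate_epi <- function(labelmap, field, acq = acq_params(), gmap = NULL) {
  stopifnot(inherits(field, "field_map"), inherits(acq, "acq_params"))
  g <- field$grid
  labelmap <- array(as.integer(labelmap), g$shape)
  template <- array(0, g$shape)
  template[labelmap == 1L] <- 0.4
  template[labelmap == 2L] <- 1.0
  nz <- g$shape[3]
  if (is.null(gmap)) {
    gmap <- array(NA_real_, g$shape)
    for (s in seq_len(nz))
      gmap[, , s] <- through_slice_gradient(field, s, acq$slice_thickness_mm)
  }
  phi <- phase_dispersion(gmap, acq$slice_thickness_mm, acq$te_s)
  atten <- abs(sinc_unnorm(array(phi / 2, g$shape)))
  atten[is.na(atten)] <- 0
  m <- template * array(atten, g$shape)
  m <- pe_shift(m, field, acq)
  nvox <- prod(g$shape)
  data <- array(0, c(g$shape, acq$n_volumes))
  if (acq$noise_sigma > 0) {
    noise <- with_seed(acq$seed,
                       stats::rnorm(2 * nvox * acq$n_volumes, 0,
                                    acq$noise_sigma))
    re <- array(noise[seq_len(nvox * acq$n_volumes)],
                c(g$shape, acq$n_volumes))
    im <- array(noise[nvox * acq$n_volumes + seq_len(nvox * acq$n_volumes)],
                c(g$shape, acq$n_volumes))
    for (v in seq_len(acq$n_volumes))
      data[, , , v] <- sqrt((m + re[, , , v])^2 + im[, , , v]^2)
  } else {
    for (v in seq_len(acq$n_volumes)) data[, , , v] <- m
  }
  structure(list(grid = g, data = data, acq = acq), class = "epi_series")
}

#' @export
print.epi_series <- function(x, ...) {
  cat("<epi_series> ", paste(x$grid$shape, collapse = " x "), " x ",
      x$acq$n_volumes, " volumes\n", sep = "")
  invisible(x)
}

# off-resonance displacement along the PE axis:
# a voxel at PE index y displays signal from y - shift, with
# shift_voxels = f_hz * total_readout_time_s * N_pe (linear interpolation,
# zero outside the field of view).
pe_shift <- function(m, field, acq) {
  g <- field$grid
  n_pe <- g$shape[acq$pe_axis]
  f <- field$values
  f[is.na(f)] <- 0
  shift <- f * acq$total_readout_time_s * n_pe
  if (acq$pe_axis == 1L) {
    ycoord <- array(rep(seq_len(n_pe), times = prod(g$shape[2:3])), g$shape)
  } else {
    ycoord <- array(rep(rep(seq_len(n_pe), each = g$shape[1]),
                        times = g$shape[3]), g$shape)
  }
  src <- ycoord - shift
  lo <- floor(src)
  fr <- src - lo
  out <- array(0, g$shape)
  gather <- function(yidx) {
    ok <- yidx >= 1 & yidx <= n_pe
    res <- array(0, g$shape)
    if (!any(ok)) return(res)
    if (acq$pe_axis == 1L) {
      i <- yidx
      j <- array(rep(rep(seq_len(g$shape[2]), each = g$shape[1]),
                     times = g$shape[3]), g$shape)
    } else {
      i <- array(rep(seq_len(g$shape[1]), times = prod(g$shape[2:3])), g$shape)
      j <- yidx
    }
    k <- array(rep(seq_len(g$shape[3]), each = prod(g$shape[1:2])), g$shape)
    res[ok] <- m[cbind(as.vector(i)[ok], as.vector(j)[ok], as.vector(k)[ok])]
    res
  }
  out <- gather(lo) * (1 - fr) + gather(lo + 1) * fr
  out
}
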
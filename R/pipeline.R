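#' Pipeline configuration
#'
#' Bundles the stage parameters of the end-to-end synthetic experiment:
#' phantom generation, dual-echo field mapping, mask construction, coil and
#' volume-shim bases, per-slice optimization over a grid of penalty weights,
#' EPI simulation and evaluation. Defaults mirror the standard protocol this
#' package models: field-map echo times 2.68/4.92 ms, EPI TE 32 ms with 5 mm
#' slices and 60 volumes, 40 mm field-map / 25 mm optimization masks,
#' 2.5 A per channel / 25 A total current bounds, and penalty weights
#' w in {0, 1e-4, 0.01, 1}.
#'
#' @param seed global integer seed; stage seeds are derived from it.
#' @param phantom list of [phantom_spec()] arguments (less `seed`).
#' @param fine_dz_mm z-resolution of the fine field-map grid on which the
#'   dual-echo acquisition is simulated and the optimization runs (default
#'   1.25 mm, so EPI slice centers fall on field-map planes, the adjacent
#'   MSE planes lie inside the excited slab, and the +/- 2.5 mm gradient
#'   stencil lands exactly on planes; must divide the EPI slice spacing).
#' @param fieldmap list: `te1_s`, `te2_s`, `noise_sigma`.
#' @param masks list: `fieldmap_diameter_mm`, `optim_diameter_mm`.
#' @param coil list of [default_loop_layout()] arguments.
#' @param sh_order volume-shim spherical-harmonic order (0-2).
#' @param w_grid penalty weights to fit (all >= 0).
#' @param control list of [shim_control()] arguments (less `w`).
#' @param acq list of [acq_params()] arguments (less `seed`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            phantom = list(),
                            fine_dz_mm = 1.25,
                            fieldmap = list(te1_s = 0.00268, te2_s = 0.00492,
                                            noise_sigma = 0.005),
                            masks = list(fieldmap_diameter_mm = 40,
                                         optim_diameter_mm = 25),
                            coil = list(),
                            sh_order = 2L,
                            w_grid = c(0, 1e-4, 0.01, 1),
                            control = list(),
                            acq = list()) {
  cfg <- structure(list(seed = as.integer(seed), phantom = phantom,
                        fine_dz_mm = fine_dz_mm, fieldmap = fieldmap,
                        masks = masks, coil = coil,
                        sh_order = as.integer(sh_order), w_grid = w_grid,
                        control = control, acq = acq),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (any(!is.finite(cfg$w_grid)) || any(cfg$w_grid < 0))
    stop("w_grid values must be finite and >= 0")
  if (!(cfg$sh_order %in% 0:2)) stop("sh_order must be 0, 1 or 2")
  if (cfg$fine_dz_mm <= 0) stop("fine_dz_mm must be > 0")
  with(cfg$masks, {
    if (optim_diameter_mm > fieldmap_diameter_mm)
      stop("optimization mask must not exceed the field-map mask")
  })
  if (!(cfg$fieldmap$te2_s > cfg$fieldmap$te1_s && cfg$fieldmap$te1_s > 0))
    stop("field-map echo times must satisfy te2_s > te1_s > 0")
  invisible(cfg)
}

#' Load a pipeline configuration from JSON or YAML
#'
#' @param path configuration file (`.json`, `.yaml` or `.yml`).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  obj <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed for YAML configs")
    yaml::read_yaml(path)
  } else stop("config must be .json or .yaml")
  do.call(pipeline_config, obj)
}

phantom_spec_from_config <- function(cfg, grid = NULL) {
  args <- cfg$phantom
  if (!is.null(grid)) args$grid <- grid
  args$seed <- cfg$seed
  do.call(phantom_spec, args)
}

#' Run the full synthetic shimming experiment
#'
#' Chains every stage on the synthetic phantom: generate the ground-truth
#' field on a fine-z field-map grid; simulate the dual-echo acquisition there
#' and estimate the field map; build the cylindrical masks; emulate the
#' scanner volume shim (spherical harmonics, pooled MSE); fit dynamic
#' slice-wise shims for every weight in `w_grid` with the loop-array
#' profiles, optimizing each EPI slice on the fine grid (adjacent-plane MSE
#' inside the excited slab, gradient stencil across it); then evaluate on
#' the EPI grid: apply the fitted currents to the ground-truth field,
#' simulate the EPI time series per condition, and compute per-slice RMSE,
#' tSNR, vertebral-level summaries, percent improvements and rank-sum
#' comparisons. Optimization always sees the *estimated* (noisy) field map;
#' evaluation uses the ground truth.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory; created if missing. `NULL` skips all
#'   file output.
#' @param seed optional override of `config$seed`.
#' @return (Invisibly) a list with the fitted conditions, per-slice metric
#'   table, level summaries, rank-sum tests and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_pipeline_config(config)

  # --- phantom: EPI grid + fine-z field-map grid --------------------------
  spec <- phantom_spec_from_config(config)
  phantom <- make_phantom(spec)
  g_epi <- phantom$grid
  nz <- g_epi$shape[3]
  ratio <- g_epi$voxel_size_mm[3] / config$fine_dz_mm
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("fine_dz_mm must divide the EPI slice spacing")
  ratio <- as.integer(round(ratio))
  nz_fine <- (nz - 1L) * ratio + 1L
  g_fine <- grid3d(c(g_epi$shape[1:2], nz_fine),
                   c(g_epi$voxel_size_mm[1:2], config$fine_dz_mm),
                   g_epi$origin_mm)
  slices_fine <- 1L + (seq_len(nz) - 1L) * ratio  # EPI slice centers
  # caudal ramp boundary at the same physical z on the fine grid
  fine_args <- config$phantom
  fine_args$grid <- g_fine
  fine_args$seed <- config$seed
  fine_args$caudal_start_slice <- slices_fine[spec$caudal_start_slice]
  phantom_fine <- make_phantom(do.call(phantom_spec, fine_args))

  # --- dual-echo acquisition and field-map estimation ---------------------
  de <- simulate_dual_echo(phantom_fine,
                           te1_s = config$fieldmap$te1_s,
                           te2_s = config$fieldmap$te2_s,
                           noise_sigma = config$fieldmap$noise_sigma,
                           seed = config$seed + 1L)
  fmap_fine <- phase_difference_fieldmap(de)
  fmap_epi <- resample_field(fmap_fine, g_epi)

  # --- masks (fine grid for optimization, EPI grid for evaluation) --------
  mask_fm_fine <- cylindrical_mask(phantom_fine$centerline,
                                   config$masks$fieldmap_diameter_mm, g_fine)
  mask_opt_fine <- cylindrical_mask(phantom_fine$centerline,
                                    config$masks$optim_diameter_mm, g_fine)
  mask_fm <- cylindrical_mask(phantom$centerline,
                              config$masks$fieldmap_diameter_mm, g_epi)
  mask_opt <- cylindrical_mask(phantom$centerline,
                               config$masks$optim_diameter_mm, g_epi)

  # --- volume shim emulation (0th-2nd order SH, pooled MSE) ---------------
  sh <- sh_basis(g_fine, config$sh_order)
  vol_control <- shim_control(w = 0, channel_bound_A = 1e3,
                              total_bound_A = 9e3, ridge = 1e-9)
  vol_fit <- shim_fit(fmap_fine, sh, mask_fm_fine, method = "volume",
                      control = vol_control)
  vol_currents <- vol_fit$currents[1, ]
  baseline_est <- combine_field(fmap_fine, sh, vol_currents)
  baseline_true_fine <- combine_field(phantom_fine$baseline_field, sh,
                                      vol_currents)
  baseline_true_epi <- resample_field(baseline_true_fine, g_epi)

  # --- dynamic slice-wise fits over the w grid (fine grid) ----------------
  coil_fine <- array_profiles(
    do.call(default_loop_layout, c(list(grid = g_fine), config$coil)), g_fine)
  coil_epi <- array_profiles(
    do.call(default_loop_layout, c(list(grid = g_epi), config$coil)), g_epi)
  ctrl_args <- config$control
  if (is.null(ctrl_args$slice_thickness_mm))
    ctrl_args$slice_thickness_mm <- g_epi$voxel_size_mm[3]
  fits <- list()
  for (w in config$w_grid) {
    ctrl <- do.call(shim_control, c(list(w = w), ctrl_args))
    fits[[paste0("w", format(w))]] <-
      shim_fit(baseline_est, coil_fine, mask_opt_fine,
               slices = slices_fine, control = ctrl)
  }

  # evaluation: fitted currents applied to the ground truth on the EPI grid
  eval_control <- do.call(shim_control, c(list(w = 0), ctrl_args))
  eval_fits <- lapply(fits, function(f)
    eval_fit_on_grid(f$currents, seq_len(nz), baseline_true_epi, coil_epi,
                     mask_opt, eval_control, w = f$w))
  vol_eval <- eval_fit_on_grid(
    matrix(0, nz, coil_epi$n_channels), seq_len(nz), baseline_true_epi,
    coil_epi, mask_opt, eval_control, w = 0, method = "volume")

  # --- EPI simulation + metrics per condition -----------------------------
  acq <- do.call(acq_params, config$acq)
  conditions <- c(list(baseline = vol_eval), eval_fits)
  per_slice <- list()
  tsnr_maps <- list()
  for (i in seq_along(conditions)) {
    cname <- names(conditions)[i]
    fit <- conditions[[i]]
    # one noise stream for all conditions: same "subject", different shim
    acq_i <- acq
    acq_i$seed <- config$seed + 100L
    ts <- stats::simulate(fit, labelmap = phantom$labelmap, acq = acq_i)
    tmap <- tsnr_map(ts, mask_opt)
    tsnr_maps[[cname]] <- tmap
    eff <- effective_field(fit)
    rmse <- vapply(seq_len(nz), function(s) slice_rmse(eff, mask_opt, s),
                   numeric(1))
    loss <- predict(fit, type = "loss", acq = acq_i,
                    slices = seq_len(nz))
    mean_loss <- vapply(seq_len(nz), function(s) {
      l <- loss$L[, , s][mask_opt$weights[, , s] > 0]
      mean(l, na.rm = TRUE)
    }, numeric(1))
    per_slice[[cname]] <- data.frame(
      condition = cname, slice = seq_len(nz),
      level = slice_levels(phantom$level_table, nz),
      rmse_hz = rmse,
      tsnr_mean = unname(per_slice_mean(tmap)),
      signal_loss_mean = mean_loss,
      sum_abs_current_A = sum_abs_by_slice(fit, nz),
      stringsAsFactors = FALSE)
  }
  per_slice <- do.call(rbind, per_slice)
  rownames(per_slice) <- NULL

  # --- level summaries, improvements, rank-sum tests ----------------------
  level_summary <- do.call(rbind, lapply(split(per_slice, per_slice$condition),
    function(d) {
      agg <- aggregate_by_level(stats::setNames(d$tsnr_mean, d$slice),
                                phantom$level_table)
      agg$condition <- d$condition[1]
      agg
    }))
  rownames(level_summary) <- NULL

  base_rmse <- per_slice$rmse_hz[per_slice$condition == "baseline"]
  tests <- list()
  for (cname in setdiff(unique(per_slice$condition), "baseline")) {
    mw <- mann_whitney_u(per_slice$rmse_hz[per_slice$condition == cname],
                         base_rmse)
    tests[[paste0(cname, "_vs_baseline")]] <- mw
  }
  if (all(c("w0", "w0.01") %in% names(fits))) {
    tests$w0_vs_w0.01 <- mann_whitney_u(
      per_slice$rmse_hz[per_slice$condition == "w0"],
      per_slice$rmse_hz[per_slice$condition == "w0.01"])
  }

  results <- list(config = config, phantom = phantom,
                  phantom_fine = phantom_fine,
                  fieldmap_fine = fmap_fine, fieldmap = fmap_epi,
                  mask_fieldmap = mask_fm, mask_optim = mask_opt,
                  volume_fit = vol_fit, fits = fits, eval_fits = eval_fits,
                  baseline_true = baseline_true_epi,
                  per_slice = per_slice, level_summary = level_summary,
                  tsnr_maps = tsnr_maps, tests = tests)

  if (!is.null(out_dir)) {
    results$manifest <- write_pipeline_outputs(results, out_dir)
  }
  invisible(results)
}

# build a shim_fit object holding given currents on an evaluation grid,
# with objective terms recomputed at those currents
eval_fit_on_grid <- function(currents, slices, baseline, profiles, mask,
                             control, w, method = "dynamic") {
  n <- profiles$n_channels
  currents <- matrix(currents, nrow = length(slices), ncol = n)
  rownames(currents) <- slices
  colnames(currents) <- profiles$names
  objective <- data.frame(slice = slices, mse_term = NA_real_,
                          grad_term = NA_real_, total = NA_real_,
                          mse_zero = NA_real_, grad_zero = NA_real_,
                          status = "ok", stringsAsFactors = FALSE)
  for (i in seq_along(slices)) {
    prob <- assemble_slice_problem(baseline, profiles, mask, slices[i],
                                   control)
    tm <- quad_terms(prob, currents[i, ])
    z0 <- quad_terms(prob, rep(0, n))
    objective$mse_term[i] <- tm$mse_term
    objective$grad_term[i] <- tm$grad_term
    objective$total[i] <- tm$total
    objective$mse_zero[i] <- z0$mse_term
    objective$grad_zero[i] <- z0$grad_term
  }
  structure(list(method = method, currents = currents, slices = slices,
                 w = w, control = control, objective = objective,
                 baseline = baseline, profiles = profiles, mask = mask,
                 channel_names = profiles$names),
            class = "shim_fit")
}

slice_levels <- function(level_table, nz) {
  out <- rep(NA_character_, nz)
  for (r in seq_len(nrow(level_table)))
    out[level_table$first_slice[r]:level_table$last_slice[r]] <-
      as.character(level_table$level[r])
  out
}

sum_abs_by_slice <- function(fit, nz) {
  out <- rep(0, nz)
  out[fit$slices] <- rowSums(abs(fit$currents))
  out
}

write_pipeline_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  phantom <- results$phantom
  write_field_nifti(phantom$baseline_field, p("baseline_field.nii"))
  write_field_nifti(results$fieldmap, p("fieldmap_estimated.nii"))
  lab <- as_nifti_volume(phantom$labelmap, phantom$grid)
  RNifti::writeNifti(lab, p("labelmap.nii"), datatype = "int16")
  write_mask_nifti(results$mask_fieldmap, p("mask_fieldmap.nii"))
  write_mask_nifti(results$mask_optim, p("mask_optim.nii"))
  write_centerline_json(phantom$centerline, p("centerline.json"))
  write_phantom_sidecar(phantom, p("phantom.json"),
                        te_s = c(results$config$fieldmap$te1_s,
                                 results$config$fieldmap$te2_s))
  for (cname in names(results$fits))
    write_shim_solution(results$fits[[cname]],
                        p(paste0("solution_", cname, ".json")))
  utils::write.csv(results$per_slice, p("per_slice_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(results$level_summary, p("level_summary.csv"),
                   row.names = FALSE)
  tests_df <- data.frame(
    comparison = names(results$tests),
    U = vapply(results$tests, `[[`, numeric(1), "U"),
    p_two_sided = vapply(results$tests, `[[`, numeric(1), "p_two_sided"),
    method = vapply(results$tests, `[[`, character(1), "method"),
    stringsAsFactors = FALSE)
  utils::write.csv(tests_df, p("tests.csv"), row.names = FALSE)

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "spineshim",
    version = as.character(utils::packageVersion("spineshim")),
    seed = results$config$seed,
    w_grid = results$config$w_grid,
    files = stats::setNames(
      as.list(unname(tools::md5sum(file.path(out_dir, files)))), files))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}
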
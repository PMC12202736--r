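# spineshim

Dynamic slice-wise B0 shimming for spinal cord MRI, with an explicit
through-slice signal-recovery penalty for multicoil (AC/DC-style) shim
arrays — plus everything needed to evaluate such shims end-to-end on a
synthetic cervico-thoracic phantom: dual-echo field-map estimation,
Biot–Savart loop arrays and spherical-harmonic volume-shim bases, the sinc
dephasing signal-loss model, a simplified GRE-EPI simulator, and the
standard evaluation metrics (per-slice B0 RMSE, temporal SNR,
vertebral-level aggregation, Mann–Whitney U comparisons).

## Who this is for

MR physicists and methods developers working on B0 shimming of the spinal
cord (or other elongated, susceptibility-challenged anatomy) who want a
self-contained, testable implementation of slice-wise constrained
least-squares shim optimization with signal-recovery weighting — without
scanner hardware or subject data.

## The model

Thick axial slices in gradient-echo EPI lose signal to through-slice
dephasing: a slice with phase dispersion φ retains sinc(φ/2) of its
signal, where φ = 2π·g·Δz·TE for a through-slice field gradient g (Hz/mm),
slice thickness Δz and echo time TE. The predicted fractional loss is
L = 1 − sinc(φ/2) (unnormalized sinc).

Dynamic shim updating solves, independently per slice s, the constrained
least-squares problem

    min_I  (1/N) Σ_a [ ΔB0,baseline + Σ_c I_c ΔB0,c ]²_a
         + w · (1/N_s) Σ_{a∈slice} [ ∂/∂z (ΔB0,baseline + Σ_c I_c ΔB0,c) ]²_a

    s.t.   |I_c| ≤ 2.5 A,   Σ_c |I_c| ≤ 25 A

where the first (MSE) term covers the masked target slice plus the
adjacent field-map planes inside the excited slab, and the second penalizes
the squared through-slice gradient on the slice (carried in µT/m; see the
methods vignette for the unit convention under which the published
operating values w ∈ {0, 1e-4, 0.01, 1} behave as reported). The objective
is an exactly convex quadratic; it is solved as a quadratic program with an
active-set polish, deterministically from a zero-current cold start.

## Worked example

```r
library(spineshim)

ph   <- make_phantom(phantom_spec())            # seeded 25-slice C3-T3 phantom
mask <- cylindrical_mask(ph$centerline, 25, ph$grid)
coil <- array_profiles(default_loop_layout(ph$grid), ph$grid)

fit <- shim_fit(ph$baseline_field, coil, mask, w = 0.01)
fit
#> Shim fit (dynamic slice-wise)
#>   channels: 15, slices: 25, w = 0.01
#>   mean |I| per slice: 16.86 A (bound 25 A)

s <- summary(fit)
c(s$mean_rmse_unshimmed_hz, s$mean_rmse_hz, s$rmse_reduction_pct)
#> 28.63  6.45  77.5
```

The fit shims each of the 25 axial slices with the 15-loop array under the
2.5 A / 25 A current limits: the mean in-mask field RMSE drops from
28.6 Hz to 6.5 Hz (a 77.5 % reduction). The signal-recovery penalty
(w = 0.01) acts where it matters — on the caudal (T1–T3) slices near the
lungs, the mean predicted in-mask signal loss falls from 0.579 (more than
half the signal gone at baseline) to 0.156:

```r
loss <- predict(fit, type = "loss")   # per-voxel L under each slice's currents
```

`coef(fit)` returns the per-slice current matrix (A), `fitted(fit)` the
effective shimmed field, `residuals(fit)` the masked residual field,
`simulate(fit, labelmap = ph$labelmap)` a noisy 60-volume EPI series for
tSNR evaluation, and `plot(fit)` the per-slice RMSE and current profiles.

The full study — field-map estimation from simulated dual-echo data,
volume-shim emulation, dynamic fits across w ∈ {0, 1e-4, 0.01, 1}, EPI
simulation and metrics — is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
res$per_slice      # tidy per-slice metrics per condition
res$level_summary  # vertebral-level tSNR summaries
res$tests          # rank-sum comparisons of RMSE distributions
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/shim.R` (`Rscript shim.R run --seed 1 --out run_dir/`).

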
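---
title: "Dynamic slice-wise B0 shimming with a through-slice signal-recovery penalty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic slice-wise B0 shimming with a through-slice signal-recovery penalty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineshim)
```

## The problem

Axial gradient-echo EPI of the cervico-thoracic spinal cord needs thick
slices (typically 5 mm) to reach workable SNR at high in-plane resolution.
Near the lungs and the vertebral discs the static field B0 is strongly
inhomogeneous, and its through-slice derivative disperses the phase of the
spins across each slice: by the echo time, a slice spanning a phase range
$\phi$ retains only a fraction $\mathrm{sinc}(\phi/2)$ of its signal. In the
lower cervical and upper thoracic cord this through-slice dephasing can
extinguish the cord signal entirely.

Multicoil shim arrays whose loops also carry DC current can reshape B0
slice by slice (dynamic shim updating, DSU). The classical per-slice
objective minimizes the masked mean squared residual field,

$$\min_I \frac{1}{N}\sum_{a=1}^{N} \Delta B_{0,\mathrm{shimmed}}(I)_a^2,
\qquad
\Delta B_{0,\mathrm{shimmed}}(I) = \Delta B_{0,\mathrm{baseline}}
 + \sum_{c=1}^{n} I_c\,\Delta B_{0,c},$$

with $\Delta B_{0,c}$ the field of channel $c$ per ampere and $I$ the
current vector. This targets in-plane homogeneity (hence geometric
distortion) but not dephasing. This package implements the extended
objective in which an explicit through-slice gradient penalty trades the
two:

$$\min_I\; \underbrace{\frac{1}{N}\sum_{a} w_a\, f(I)_a^2}_{\text{mse\_term}}
 \;+\; w\,\underbrace{\frac{1}{N_s}\sum_{a \in \text{slice}} w_a\,
 g(I)_a^2}_{\text{grad\_term}},$$

where $f$ is the shimmed field (Hz) over the masked target slice and its
directly adjacent field-map planes, $g$ is the through-slice gradient of the
shimmed field on the target slice, and $w \ge 0$ balances signal recovery
against homogeneity. The predicted fractional signal loss is
$L = 1 - \mathrm{sinc}(\phi/2)$ with $\phi = 2\pi\, g\, \Delta z\,
\mathrm{TE}$ ($g$ in Hz/mm; unnormalized sinc, so $L(2\pi) = 1$), assuming a
rectangular slice profile, uniform spin density, and a field varying
linearly through the slice.

## Units and the meaning of w

Fields are carried in Hz everywhere; conversion to radians happens only in
the signal model. Inside the objective, however, the penalty gradient is
expressed in **uT/m**, the conventional unit for first-order shim terms
(1 Hz/mm = 23.4866 uT/m for protons), so `grad_term` is in (uT/m)^2 while
`mse_term` is in Hz^2. The source of the objective does not fix the
normalization of the gradient term or the units of $w$; we adopt this
mixed-unit convention because it is the one under which the operating
values of $w$ reported for spinal-cord protocols behave as described:

* `w = 0` - plain slice-wise MSE shimming;
* `w = 1e-4` - indistinguishable from `w = 0`;
* `w = 0.01` - buys substantial through-slice signal recovery at a
  percent-level cost in in-plane RMSE (the recommended operating point);
* `w = 1` - sacrifices in-plane homogeneity (and with it geometric
  fidelity) for marginal further recovery, and demands much higher
  currents.

Under an Hz/mm reading of the gradient the same numerical values of $w$ sit
three orders of magnitude below the active range of the trade-off curve for
any plausible cord/coil configuration we simulated, so that convention
cannot reproduce the reported regimes.

## Optimization

The objective is an exactly convex quadratic in $I$. Constraints are a
per-channel box $|I_c| \le 2.5$ A and a total budget
$\sum_c |I_c| \le 25$ A (both configurable; the sum form is adopted for the
"25 A for all channels" style limit of multicoil shim amplifiers). The
solver proceeds in three stages:

1. **Interior candidate.** The unconstrained stationary point of the
   regularized quadratic, accepted when feasible. This is exact to machine
   precision, which matters for cancellation tests where the baseline lies
   in the coil span.
2. **Split-variable QP.** Otherwise the problem is solved as a QP in
   $(p, m)$ with $I = p - m$, $0 \le p, m \le 2.5$, $\mathbf{1}'(p+m) \le
   25$ (`pracma::quadprog`), and the solution is projected onto the exact
   feasible set (the QP leaves ~1e-4 A slack at active bounds).
3. **Active-set polish.** The KKT system is re-solved with the QP's active
   constraints fixed, restoring machine precision at the bounds.

Cold start is the zero vector and every stage is deterministic. If the
solver fails on a slice, that slice keeps zero currents and is flagged - a
failed slice is acquired unshimmed rather than with unvetted currents. A
returned solution is never worse than no shim.

**Current regularization.** Cord-shim design matrices are severely
ill-conditioned: a thin cylindrical ROI seen by 15 distant loops has
effective rank well below 15, and the exact minimizer of the unregularized
problem pours tens of amperes into near-null channel combinations for
residual gains below 1%. Practical shim optimizers never operate there
(finite iteration counts and tolerances act as implicit regularization), and
hardware current budgets make such solutions undesirable. The solver
therefore adds a Tikhonov term `ridge * |I|^2` with default
`ridge = 0.1` Hz^2/A^2 - a 5 A budget costs the equivalent of a 1.6 Hz
RMSE term - which keeps solutions in the few-ampere regime while changing
the attainable residual only at the percent level. Setting
`ridge = 1e-12` recovers the pure minimum-norm tie-break (used by the
oracle-equivalence and exact-cancellation tests, where the target is the
unregularized optimum). Note one side effect: because the solver objective
includes the ridge, the *reported* `mse_term` is only guaranteed monotone
non-decreasing in $w$ for the pure objective; the Pareto property is
asserted there.

**Gradient stencil and adjacency.** The through-slice gradient of slice
$s$ is the symmetric difference over $\pm\Delta z/2$ about the slice
center, with the two planes obtained by linear interpolation between the
field's z-planes (one-sided at the volume ends, flagged). Optimization is
intended to run on a fine-z field-map grid (the pipeline default is
1.25 mm planes under 5 mm EPI slices, emulating the dense-slice field map
such protocols acquire): EPI slice centers then fall exactly on planes,
the adjacent-plane MSE covers planes *inside* the excited slab, and the
$\pm 2.5$ mm stencil spans the slab. Both choices matter: with adjacency
at $\pm$ one EPI slice (5 mm away) the MSE term becomes a full surrogate
of the gradient penalty for locally linear fields and $w$ loses its
leverage, while planes inside the slab leave the penalty its own role -
selecting, among near-equal-MSE solutions, those whose residual is not
antisymmetric across the slab.

Normalizations: $N$ counts the positive-weight voxels of the MSE region,
$N_s$ those of the target slice, so the meaning of $w$ is independent of
mask size. Under duplicated (rank-deficient) channels the ridge selects the
even, minimum-norm split. Empty masked slices are rejected; invalid field
voxels (no signal, outside a resampled extent) are excluded from all sums
and never treated as 0 Hz.

## The synthetic phantom

All claims in this package are exercised on a seeded synthetic phantom; no
external data are needed. The phantom emulates, on a 64 x 64 x 25 grid at
2 x 2 x 5 mm (25 axial slices spanning C3-T3):

* a cord of radius 4 mm following a bowed centerline inside a body
  ellipse;
* a smooth low-order background polynomial (what a scanner's volume shim
  mostly removes);
* spatially periodic disc perturbations: 25 Hz at a source line 12 mm
  anterior to the cord (the bone-tissue interface at the posterior disc
  tip), period 20 mm, Gaussian in-plane decay over 10 mm - giving in-cord
  amplitudes around 10-15 Hz and through-slice gradients of a few Hz/mm;
* a caudal lung-proximity ramp of 10 Hz/mm below the T2 boundary, so the
  lowest slices suffer near-complete baseline dephasing at TE = 32 ms /
  5 mm while the total field stays inside the +/-223 Hz unambiguous range
  of the 2.68/4.92 ms dual-echo field map;
* dual-echo complex GRE data with optional complex Gaussian noise.

The amplitudes were chosen once so that the phantom reproduces the
canonical cervico-thoracic pattern reported for 3 T - minimal signal loss
from C4 to T1, severe loss at T2/T3, DSU RMSE reductions on the ~70-90%
scale, currents below the hardware budget at small $w$ - and are plausible
for 3 T, but they are not fitted to any in-vivo dataset. What the phantom
deliberately omits: susceptibility-computed fields from a tissue model,
respiration-induced field dynamics, physiological signal fluctuations,
realistic anatomy, T2* decay and k-space effects in the EPI simulator.
Passing tests therefore demonstrate the correctness and internal
consistency of the optimizer and forward models under controlled
conditions, not in-vivo performance.

The simulated 15-loop array places fourteen 45 mm loops in two staggered
posterior columns over the rostral z-range and a single loop near the
caudal end (thoracic coverage is deliberately sparse, the known weakness of
cervical arrays), on a cylinder of radius 60 mm - the posterior neck
surface sits roughly 6 cm from the cord. Coils much further out (we
examined 120 mm) cannot steer the through-slice gradient at the cord
within realistic current limits, which makes the penalty physically inert;
the 60 mm default keeps the array in the regime where published multicoil
results operate. Loop fields are polygonal Biot-Savart sums (only $B_z$
contributes to off-resonance); the scanner's volume shim is emulated by a
0th-2nd order real solid-harmonic basis and a single pooled-MSE solve.

## The pipeline and its evaluation design

`run_pipeline()` chains: phantom -> dual-echo simulation on the fine grid
-> conjugate-product field map (no spatial unwrapping; the +/-1/(2 dTE)
range is documented and respected by the phantom) -> cylindrical masks
(40 mm field-map mask, 25 mm optimization mask) -> SH volume shim ->
dynamic fits for $w \in \{0, 10^{-4}, 0.01, 1\}$ -> EPI simulation (60
volumes) -> metrics. Two design points deserve note:

* optimization always sees the *estimated* (noisy) field map, while
  evaluation applies the fitted currents to the ground-truth field - the
  synthetic analogue of optimizing on an acquired map and being judged by
  the true physics;
* all shim conditions share one EPI noise stream per run (a paired,
  same-subject design), so condition contrasts are not diluted by
  independent noise.

Metrics are the per-slice in-mask B0 RMSE (Hz), voxel-wise temporal SNR
(sample-SD; undefined voxels excluded), vertebral-level aggregation (equal
slice weighting), percent improvement over baseline, and two-sided
Mann-Whitney U comparisons of per-slice RMSE distributions (exact for
small tie-free samples, tie- and continuity-corrected normal approximation
otherwise).

Problem sizes: the default study uses the 25-slice phantom (fine grid
64 x 64 x 97), 15 channels, 60 EPI volumes; the full pipeline runs in
about a minute on one CPU, and the package's test suite - including two
full pipeline runs and a grid-search oracle sweep - in about two minutes.

## Known limitations

* The penalty's unit convention (uT/m) is a calibration to reported
  operating behavior, not a derivation; a different coil or anatomy may
  prefer a different $w$ scale.
* The total-current constraint is implemented as $\sum_c |I_c|$; amplifier
  group limits of other forms are not modeled.
* No spatial phase unwrapping: fields beyond +/-223 Hz (for the default
  echo times) alias, by design.
* The EPI distortion model is the first-order voxel-shift approximation
  along the phase-encode axis (`shift = f x readout-time constant x
  N_pe`, linear interpolation, no Jacobian intensity correction), and
  in-plane dephasing is not modeled.
* Respiration-resolved (real-time) shimming and scanner-gradient/multicoil
  joint optimization are out of scope.
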
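Package: spineshim
Title: Dynamic Slice-Wise B0 Shimming with Through-Slice Signal Recovery for Spinal Cord MRI
Version: 1.0.0
Authors@R:
    person("Marc", "Aubertin", email = "spineshim@protonmail.com",
           role = c("aut", "cre"))
Description: Tools for dynamic slice-wise B0 shimming of the cervico-thoracic
    spinal cord with multicoil shim arrays. Implements per-slice constrained
    least-squares shim current optimization with an explicit through-slice
    gradient (signal-recovery) penalty, the sinc dephasing signal-loss model
    and a simplified gradient-echo EPI simulator (attenuation, phase-encode
    distortion, Rician noise), dual-echo field-map estimation, cylindrical and
    soft spinal-cord masks, Biot-Savart loop-array and spherical-harmonic shim
    bases, and evaluation metrics (per-slice B0 RMSE, temporal SNR,
    vertebral-level aggregation, Mann-Whitney U comparison). A seeded synthetic
    spinal-cord phantom exercises the whole pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    RNifti,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
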
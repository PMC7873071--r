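# pact3d

Simulation, calibration, reconstruction and analysis for hemispherical-array
three-dimensional photoacoustic computed tomography (3D-PACT).

In 3D-PACT a nanosecond laser pulse deposits energy in tissue; optical
absorbers (chiefly hemoglobin) convert it to a pressure transient that
propagates as wideband ultrasound and is recorded by transducers surrounding
the tissue. The system modeled here detects with 1024 elements on four
83-degree arcs of a 130-mm-radius hemisphere (2.25 MHz center frequency,
98% one-way bandwidth, 40 MHz sampling) and rotates the arcs coaxially
through 90 degrees at a 10-Hz laser rate, sweeping out a densely sampled
hemispherical detection matrix. The package implements the full
computational chain of such an instrument, exercised entirely on simulated
acquisitions:

* **geometry / simulate** — parametrization of the four-arc array and its
  scan; an analytic N-wave forward model (`p(t) ∝ (r − ct)/2r` inside the
  sphere's support) with a Gaussian band-pass detector response, digital
  phantoms (breast-mimicking tumors with μa = 0.105 vs 0.05 cm⁻¹;
  branching vessels down to 0.4 mm), and 4D functional series generators.
* **calibrate** — time-of-flight geometric self-calibration: from the
  propagation times of a point source at M positions, jointly estimate the
  sound speed c, the source positions, and one radial factor α_n per
  element (`|s_m − α_n r_n| = c t_{m,n}`), by iterating least-squares
  steps on the locally linearized distance equations.
* **reconstruct** — universal back-projection of the filtered term
  `b(t) = 2p(t) − 2t dp/dt` with solid-angle and scan-quadrature weights,
  distance-dependent antialiasing (2× channel interpolation plus a
  `min(f_max, f_max d0/d)` low-pass), and a two-pass dual-speed-of-sound
  correction: single-speed image → tissue-surface extraction →
  half-ellipsoid fit → two-segment straight-ray delays with tissue and
  coupling-fluid speeds inside/outside the surface. Default voxels:
  0.13 mm isotropic.
* **motion** — time-gated motion correction: per-firing first-arrival
  times, 3-point median filtering, strict >0.025 µs difference gating, and
  splicing of motionless segments from repeated scans.
* **postprocess** — exponential depth compensation (e^(0.81·depth cm)
  brain, e^(0.72·depth cm) breast), a pluggable denoiser, multiscale 3D
  Frangi vesselness, self-normalized 0.2/0.8 blending, and maximum
  amplitude projections.
* **funcimg** — 0.008–0.09 Hz zero-phase Butterworth bandpass, global
  signal regression, ROI connectivity matrices, fractional-change traces,
  and stimulation block averages.

File formats: HDF5 sinograms (schema documented in `?write_sinogram`),
NIfTI volumes and 4D series, JSON calibration reports and provenance
sidecars, YAML/JSON run configs. A thin command-line wrapper is installed
at `inst/cli/pact3d.R` with subcommands `simulate`, `calibrate`,
`reconstruct`, `motion-correct`, `postprocess`, `functional`, `report`.

## Worked example

Simulate a reduced scan of a 0.3-mm absorber, reconstruct it, then
self-calibrate a radially perturbed array from exact point-source times:

```r
library(pact3d)

cfg  <- system_config(elements_per_arc = 32)          # 4 x 32 = 128 elements
geom <- build_nominal_array(cfg)
traj <- scan_trajectory(angular_speed = (pi / 2) / 0.4, duration = 0.4)
mat  <- make_detection_matrix(geom, traj)             # 5 firings over 90 deg

ph <- phantom(spheres = data.frame(x = 5, y = 0, z = -5,
                                   radius = 0.3, mu_a = 1))
sg <- simulate_scan(ph, mat, c = 1.5, noise_sd = 0)

grid <- volume_grid(c(33, 33, 33), voxel_size = 0.13,
                    origin = c(5, 0, -5) - 16 * 0.13)
vol <- ubp_backproject(sg, grid)
print(vol)
#> volume: 33 x 33 x 33 voxels at 0.13 mm, origin (2.92, -2.08, -7.08) mm
#>   values in [-0.2083, 1.216]
idx <- which(vol$values == max(vol$values), arr.ind = TRUE)[1, ]
cat("peak voxel center (mm):", grid$origin + (idx - 1) * grid$voxel_size, "\n")
#> peak voxel center (mm): 5 0 -5
```

The reconstructed maximum lands on the true absorber center to within one
voxel. Calibration recovers percent-level radial manufacturing defects:

```r
set.seed(1)
alpha_true <- runif(128, 0.98, 1.02)      # +/-2% radial defects
sources <- rbind(c(10, 0, 5), c(-8, 6, 12), c(0, -9, 18), c(4, 7, -3),
                 c(-12, -5, 8), c(6, -11, 15), c(-3, 12, 2), c(9, 9, 20))
perturbed <- apply_radial_factors(geom, alpha_true)
ses <- make_point_source_session(sources, perturbed, response = NULL, c = 1.5)
meas <- tof_measurement(ses$tof, initial_c = 1.515,   # c guess 1% off
                        initial_source_positions = sources + 1,
                        nominal_element_positions = geom$positions)
cal <- run_jacobi_calibration(meas, n_iterations = 50)
print(cal)
#> calibration state: c = 1.499219 mm/us, 8 sources, 128 elements
#>   iteration 50, RMS residual 1.704e-14 us, alpha in [0.98001, 1.01918]
cat("max radial-factor error:", max(abs(cal$alpha - alpha_true)), "\n")
#> max radial-factor error: 0.0005311956
```

The residual is the RMS mismatch between predicted and measured
propagation times; 1e-14 µs means the estimated geometry reproduces the
data to machine precision, and every radial factor is recovered to a few
parts in 10⁴.

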
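---
title: "Models and methods behind pact3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pact3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pact3d)
```

pact3d reimplements, on simulated data, the computational chain of a
three-dimensional photoacoustic computed tomography (3D-PACT) system built
around four arc-shaped ultrasonic arrays on a rotating hemisphere: geometric
self-calibration of the array from point-source times of flight, universal
back-projection (UBP) reconstruction with antialiasing and a
dual-speed-of-sound correction, time-gated motion correction, vascular
contrast enhancement, and resting-state functional connectivity analysis.
This vignette records the models, the numerical choices, and the places
where the design was genuinely open.

## Coordinate frame and detection geometry

The frame is right-handed with the origin at the hemisphere center, +Z
pointing up toward the imaging platform, and the mechanical scan rotating
about +Z. All transducer elements sit at Z less than or equal to 0. Each of
the four 256-element arcs lies in a plane containing the Z axis, with
elements uniformly spaced in elevation; the defaults encode the hardware:
130-mm radius, 83-degree arcs, 0.74-mm pitch, 2.25-MHz center frequency
with 98% one-way bandwidth, 40-MHz sampling, 10-Hz laser, and a 90-degree
scan that sweeps the four arcs into a densely sampled hemispherical
detection matrix.

**Arc elevation placement.** The printed hardware description fixes the arc
span (83 degrees) but not where on the meridian the arc sits. We place the
top element at the equator (elevation 0) so each arc spans elevations -83
to 0 degrees, leaving a 7-degree polar gap. Two observations force this
choice. Mechanically, four rigid arcs mounted 90 degrees apart cannot all
pass through the pole - they would intersect; a polar gap is the only
self-consistent layout. Numerically, an equator-reaching arc yields a
point-spread function with X/Y/Z full widths at half maximum of
338/338/339 um at the grid center (0.3% spread), matching the near-isotropy
the instrument measured (390 vs 370 um); a pole-touching arc instead
oversamples the polar direction and misses the equatorial band, inflating
the lateral width by 12-17%. The placement remains configurable
(`arc_elevation_top` in `system_config()`).

## Forward model

The simulator is analytic. A uniform spherical absorber of radius $a$ at
distance $r$ radiates the classic bipolar N-wave
$p(t) = A\,(r - ct)/(2r)$ for $|r - ct| < a$, zero otherwise, with
amplitude proportional to the absorption coefficient times the local
fluence. Cylinders are discretized into spheres spaced at half their radius
with amplitude normalization. Elements are treated as points at their
centers: the 0.6 x 0.7 mm aperture is small against the 0.67-mm center
wavelength at the 130-mm range, and the point model keeps a closed form
usable as an oracle.

The electro-acoustic response is a zero-phase band-pass with a Gaussian
amplitude spectrum: unit gain at 2.25 MHz, -6 dB full width equal to the
98% fractional bandwidth, and a mirrored-lobe construction that makes the
DC gain exactly zero. Only center frequency and bandwidth are printed for
the hardware; the spectral shape is our choice and configurable.

Fluence is uniform by default (which keeps the forward model linear in the
absorption map, the property most tests lean on); an exponential depth
decay with the breast-average 0.9 cm^-1 coefficient is available for the
breast preset. Noise is additive white Gaussian per sample, seeded; the
instrument's noise spectrum is not characterized in print, so the level is
a free fixture parameter recorded in provenance.

## Time-of-flight self-calibration

Manufacturing defects displace each element mainly along the radial axis
(the arrays are made by saw dicing), so calibration estimates a sound speed
$c$, the unknown point-source positions, and one radial factor
$\alpha_n$ per element, from the $M \times N$ matrix of first-arrival
times. The distance equations
$|s_m - \alpha_n r_n|^2 = (c\,t_{m,n})^2$ are assumed locally linear
around the initial estimates (sound speed from water temperature, sources
from preliminary images, elements from the manufacturer's drawing).

**Identifiability.** The data determine the parameters only up to a global
scale: $(kc,\; ks_m,\; k\alpha_n)$ predicts identical times for any
$k > 0$. Any consistent solver therefore needs an anchor; we fix the gauge
explicitly by rescaling $(c, s_m, \alpha_n)$ after each iteration so that
the mean radial factor is 1 - an exact gauge transformation that leaves
every predicted time (and hence the residual) unchanged while pinning the
solution to the nominal radius scale. The anchored solution then differs
from the truth only by the sample mean of the true factors (about 4e-4 for
percent-level defects).

**Why the default is a joint step.** The three printed closed-form updates
(mean-of-ratios for $c$; differenced, linearized least squares for the
sources; a per-element quadratic for $\alpha_n$) are implemented exactly
(`update_speed_of_sound()`, `update_source_locations()`,
`update_radial_factors()`, and `run_jacobi_calibration(method =
"block")`). Iterating them in alternation, however, stalls on a weakly
determined mode - a common translation of all sources compensated by an
elevation-patterned shift of the radial factors plus a small speed change -
leaving relative errors near 1e-3 when the initial speed is off by 1% and
the sources by 2 mm. We verified this across update orders, source-update
variants (consecutive differencing as printed, all-pairs differencing, and
per-source Gauss-Newton), gauge renormalization, and nested inner loops.
The default (`method = "joint"`) therefore takes the local-linearity
assumption at face value: each iteration solves the linearization of all
equations in all unknowns at once by least squares. The Jacobian is an
arrow matrix (each $\alpha_n$ touches only its own column), so a Schur
complement reduces the step to O(MN) work; a tiny Tikhonov term keeps the
solve well posed along the scale gauge, which the mean-factor
normalization then fixes. On exact times this converges
to machine-zero residual with a monotone residual trace, recovering
percent-level radial defects to a few times 1e-4 in 50 iterations for
M = 8 sources and N = 1024 elements.

The first-arrival picker triggers at 5 times the median absolute deviation
of a leading noise window (the hardware description does not specify a
picker); the time threshold and the fixture default of eight source
positions follow the same convention as the motion module.

## Reconstruction

UBP back-projects the filtered term $b(t) = 2p(t) - 2t\,\mathrm{d}p/\mathrm{d}t$
(temporal derivative by central differences; delays interpolated linearly,
with nearest-sample lookup available for oracle comparisons) along
spherical shells, accumulating with solid-angle weights
$\cos\theta / d^2$ normalized per voxel. Two quadrature details matter:

* **Pose area weights.** The rotational scan crowds virtual poses together
  near the pole (a pose at elevation $\theta$ sweeps an azimuthal arc
  proportional to $\cos\theta$). Each pose is therefore weighted by
  $\cos\theta$ in addition to the solid-angle factor. Without it the polar
  direction dominates the aperture and the point-spread function is ~70%
  anisotropic.
* **Antialiasing.** Outside the well-resolved field of view the angular
  sampling violates the spatial Nyquist criterion. Before back-projection
  the sinogram is upsampled 2x along the element index within each arc and
  low-pass filtered at $f_\mathrm{cut}(d) = \min(f_\mathrm{max},
  f_\mathrm{max} d_0 / d)$, where $d$ is the largest distance from the
  scan axis served by the grid and $d_0$ (default 10 mm, the ~2-cm
  field of view of a 5-s scan) is the well-resolved radius. The governing
  cutoff formula is not printed for this instrument; the law and its
  constants are configuration, and the stated ~2-cm / ~4-cm fields of view
  serve as calibration checks only.

Volumes default to 0.13-mm isotropic voxels.

**Dual speed of sound.** A first single-speed pass feeds a surface
extractor that marches 5-voxel detection windows toward the tissue -
horizontally inward toward the scan axis and vertically upward from the
detector side - and marks the first window whose mean exceeds the
background mean plus 3 standard deviations (background taken from the x-y
corner regions a centered subject cannot reach; window length and
threshold are our choices, unstated in print). Rays that start inside
tissue, or windows reached without a clean background prefix, are dropped.
The point cloud is fitted with an axis-aligned, axis-centered half
ellipsoid by linear least squares on the quadric
$\theta_1 x^2 + \theta_2 y^2 + \theta_3 z^2 + \theta_4 z = 1$; the
algebraic fit is used as-is because a geometric refinement demonstrably
drifts along the weakly determined height/vertical-axis direction when the
cloud covers only the lower half. The final pass assigns the tissue speed
inside the fitted half ellipsoid and the coupling-fluid (D2O) speed
outside, with exact quadratic ray-ellipsoid intersection giving the
two-segment straight-ray delay; refraction bending is out of scope.

## Time-gated motion correction

First-arrival times are computed per firing and channel with the shared
picker and summarized by the channel median. The summary sequence is
median-filtered (kernel 3) and first-differenced along the firing sequence;
differences strictly greater than 0.025 us (one temporal sample) mark a
motion event, and both firings forming the jump are removed. The printed
description is ambiguous about whether the differencing runs across
channels within a firing or across firings; we difference across firings,
which matches the use of the gate for removing whole motion events, and
remove whole firings (motion displaces the whole subject). Motionless
segments of repeated scans are spliced earliest-scan-first (configurable)
into a full-scan sinogram with a per-firing coverage report.

## Contrast enhancement

The post-processing chain is depth compensation, denoising, Frangi
vesselness, and blending:

* Depth compensation multiplies tissue voxels by $e^{k\,\mathrm{depth(cm)}}$
  with $k = 0.81$ (brain) or $0.72$ (breast). Depth is the radial distance
  to the fitted surface measured along the ray from the ellipsoid center
  (only "depth" is printed; the radial metric is our choice), and only
  tissue voxels are compensated. Without a surface, depth runs from the
  volume's top face and the result is flagged.
* The denoiser is a registry; the default is separable multi-level Haar
  soft-thresholding with the universal threshold estimated from the finest
  detail band. The sparse 4D collaborative filter used on the instrument's
  images is deliberately out of scope; the chain is what is tested, and
  the denoiser is replaceable.
* Vesselness is the standard three-eigenvalue Frangi score in [0, 1] with
  bright-vessel polarity, sensitivity constants 0.5/0.5 and the
  structureness constant at half the maximal Hessian norm per scale
  (the citation for the filter prints no parameters), maximized over
  scales 0.2-1.0 mm to match the 0.4-2-mm vessels of interest.
* Blending: the vesselness volume is normalized to its own peak, rescaled
  to the original's peak ("self-normalized" is not defined in print; this
  contract is explicit and configurable), and added with weight 0.2 to the
  depth-compensated original weighted 0.8.

## Functional analysis

Volumetric series at 0.5 Hz are bandpassed per voxel with a second-order
Butterworth design (0.008-0.09 Hz) applied forward-backward. Zero-phase
filtering squares the magnitude response (effective order 4); a single
causal pass is available where the printed second-order response is wanted
verbatim. Global signal regression removes the brain-mask mean series with
an intercept (whether the original analysis included one is unstated; we
include it and say so). Region signals are voxel means per label; the
connectivity matrix is Pearson correlation (rank correlation available).
The pipeline guard enforces the order bandpass, then regression, then
region averaging, because averaging before regression changes the result.
Fractional-change traces and 24-s block averages (12 phase bins at 0.5 Hz)
cover the stimulation and hypoxia designs.

## What the generator emulates, and what it does not

The synthetic-data module reproduces the acquisition geometry, timing,
band-limited detection, and the study's phantom contrasts (tumor spheres of
0.105 cm^-1 in a 0.05 cm^-1 background at 2 cm depth, including a 1-mm
tumor; branching vessels down to 0.4 mm), plus functional designs: resting
series of 240 frames with contralateral region pairs sharing band-limited
(0.01-0.08 Hz) latent signals (shared weight 0.7), 24-s boxcar stimulation,
and a 20% hypoxic dip. It does not simulate full-wave acoustics
(reflections, shear, skull aberration), speckle, element directivity, or
physiological confounds, so green tests certify the computational chain -
not instrument performance on tissue.

## Problem sizes and numerical tolerances used by the tests

The suite exercises reduced instances chosen to probe each property: the
back-projector is validated against a naive triple-loop reference on a
16^3 grid with 32 elements and 5 firings (agreement to 1e-9 relative); the
point-spread function runs the full 1024-element array with 13 firings on
a 64^3, 0.13-mm grid; the amplitude-ratio experiment uses 256 elements and
25 firings on a 0.5-mm grid; calibration recovery runs M = 8 and N = 1024
with 50 iterations; two-segment delays are checked against a 1e5-step
ray-marching integrator on 100 random pairs (1e-4 mm); motion gating is
compared with a brute-force evaluation of the rule on 1000 seeded
sequences. Seeds are fixed throughout; simulations are deterministic given
a seed.

## Known limitations

Cylinder discretization approximates vessel waveforms to a few percent;
the antialiasing constants are a documented parametrization, not the
instrument's unpublished formula; the half-ellipsoid fit constrains the
center to the scan axis (the full 9-parameter quadric is out of scope);
straight-ray dual-speed delays ignore refraction; and the block
calibration scheme is retained only for methodological comparison - its
weakly determined mode caps its accuracy below the joint default.
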
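#' Analytic N-wave from a uniformly absorbing sphere
#'
#' Closed-form pressure trace at a point detector from a uniform spherical
#' absorber: the classic bipolar N-shaped transient
#' \deqn{p(t) = A \, (r - c t) / (2 r), \quad |r - c t| < a,}
#' and zero otherwise, where `r` is the detector-center distance, `a` the
#' sphere radius and `c` the sound speed. The amplitude `A` scales linearly
#' with the optical absorption coefficient under uniform fluence. The trace
#' crosses zero exactly at the center arrival time `t = r/c` and has support
#' of duration `2 a / c`.
#'
#' @param center Sphere center, length-3 mm.
#' @param radius Sphere radius, mm.
#' @param amplitude Peak-scale amplitude (arbitrary pressure units).
#' @param element_position Detector position, length-3 mm.
#' @param t_grid Uniform time grid, microseconds.
#' @param c Speed of sound, mm/us.
#' @return Numeric vector of pressure samples on `t_grid`.
#' @export
sphere_signal <- function(center, radius, amplitude, element_position,
                          t_grid, c = 1.5) {
  stopifnot(length(center) == 3, length(element_position) == 3, radius > 0)
  r <- sqrt(sum((element_position - center)^2))
  if (r <= radius)
    stop("detector lies inside the sphere; the N-wave form assumes r > a",
         call. = FALSE)
  u <- r - c * t_grid
  p <- numeric(length(t_grid))
  on <- abs(u) < radius
  p[on] <- amplitude * u[on] / (2 * r)
  p
}

#' Transducer impulse response model
#'
#' Band-pass electro-acoustic response characterized by center frequency and
#' one-way fractional bandwidth. The default model is a zero-phase Gaussian
#' amplitude spectrum with unit peak gain at the center frequency, -6 dB
#' full width equal to `fractional_bandwidth * center_frequency`, and exact
#' DC rejection.
#'
#' @param center_frequency MHz.
#' @param fractional_bandwidth One-way fractional bandwidth in (0, 2).
#' @param model Spectral model tag; only `"gaussian-bandpass"` is built in.
#' @return A `pact_response` object.
#' @export
transducer_response <- function(center_frequency = 2.25,
                                fractional_bandwidth = 0.98,
                                model = "gaussian-bandpass") {
  if (fractional_bandwidth <= 0 || fractional_bandwidth >= 2)
    stop("'fractional_bandwidth' must be in (0, 2)", call. = FALSE)
  if (!identical(model, "gaussian-bandpass"))
    stop("unknown response model: ", model, call. = FALSE)
  structure(list(center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth,
                 model = model),
            class = "pact_response")
}

# Amplitude spectrum of the Gaussian band-pass at frequencies f (MHz).
# Mirror-image construction makes the gain exactly zero at DC while keeping
# unit gain at +/- fc to within exp(-2 fc^2 / sigma^2).
response_gain <- function(f, response) {
  fc <- response$center_frequency
  halfw <- response$fractional_bandwidth * fc / 2
  sigma <- halfw / sqrt(2 * log(2))  # -6 dB (amplitude 1/2) at fc +/- halfw
  exp(-(abs(f) - fc)^2 / (2 * sigma^2)) - exp(-(abs(f) + fc)^2 / (2 * sigma^2))
}

#' Apply the transducer band-pass response to pressure traces
#'
#' Zero-phase filtering in the frequency domain. Accepts a single trace or a
#' matrix of traces in columns.
#'
#' @param trace Numeric vector, or matrix with traces in columns.
#' @param response A `pact_response`.
#' @param sampling_rate Sampling rate in MHz.
#' @return Filtered trace(s), same shape as the input.
#' @export
apply_transducer_response <- function(trace, response, sampling_rate = 40) {
  stopifnot(inherits(response, "pact_response"))
  x <- as.matrix(trace)
  T <- nrow(x)
  if (T < 2) stop("trace must have at least 2 samples", call. = FALSE)
  f <- c(seq(0, floor(T / 2)), seq(-ceiling(T / 2) + 1, -1)) * sampling_rate / T
  g <- response_gain(f, response)
  out <- Re(stats::mvfft(stats::mvfft(x) * g, inverse = TRUE)) / T
  if (is.matrix(trace)) out else drop(out)
}

#' Digital phantom of spheres and cylinders
#'
#' @param spheres data.frame with columns `x, y, z` (center mm), `radius`
#'   (mm), `mu_a` (absorption, cm^-1); may be empty.
#' @param cylinders data.frame with columns `x1,y1,z1,x2,y2,z2` (endpoints
#'   mm), `radius` (mm), `mu_a`; may be empty.
#' @param background_mu_a Background absorption, cm^-1.
#' @param reduced_scattering Reduced scattering coefficient, cm^-1 (metadata).
#' @param fluence_decay Exponential fluence decay constant along depth,
#'   cm^-1 (0 = uniform fluence).
#' @return A `pact_phantom`.
#' @export
phantom <- function(spheres = NULL, cylinders = NULL, background_mu_a = 0,
                    reduced_scattering = 5, fluence_decay = 0) {
  empty_sph <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                          radius = numeric(), mu_a = numeric())
  empty_cyl <- data.frame(x1 = numeric(), y1 = numeric(), z1 = numeric(),
                          x2 = numeric(), y2 = numeric(), z2 = numeric(),
                          radius = numeric(), mu_a = numeric())
  spheres <- if (is.null(spheres)) empty_sph else as.data.frame(spheres)
  cylinders <- if (is.null(cylinders)) empty_cyl else as.data.frame(cylinders)
  if (nrow(spheres) && any(spheres$radius <= 0))
    stop("sphere radii must be positive", call. = FALSE)
  if (nrow(cylinders) && any(cylinders$radius <= 0))
    stop("cylinder radii must be positive", call. = FALSE)
  if ((nrow(spheres) && any(spheres$mu_a < 0)) ||
      (nrow(cylinders) && any(cylinders$mu_a < 0)) || background_mu_a < 0)
    stop("absorption coefficients must be nonnegative", call. = FALSE)
  structure(list(spheres = spheres, cylinders = cylinders,
                 background_mu_a = background_mu_a,
                 reduced_scattering = reduced_scattering,
                 fluence_decay = fluence_decay),
            class = "pact_phantom")
}

# Discretize cylinders into overlapping spheres (spacing = radius/2) with
# amplitude normalization so total emitted amplitude per unit length matches
# a chain of unit spheres.
phantom_as_spheres <- function(ph) {
  sph <- ph$spheres
  if (nrow(ph$cylinders)) {
    extra <- lapply(seq_len(nrow(ph$cylinders)), function(i) {
      cy <- ph$cylinders[i, ]
      a <- c(cy$x1, cy$y1, cy$z1); b <- c(cy$x2, cy$y2, cy$z2)
      L <- sqrt(sum((b - a)^2))
      n <- max(2L, ceiling(L / (cy$radius / 2)) + 1L)
      tt <- seq(0, 1, length.out = n)
      # overlap factor 2 (spacing r/2 vs diameter) -> normalize amplitude
      data.frame(x = a[1] + tt * (b[1] - a[1]),
                 y = a[2] + tt * (b[2] - a[2]),
                 z = a[3] + tt * (b[3] - a[3]),
                 radius = cy$radius, mu_a = cy$mu_a / 4)
    })
    sph <- rbind(sph, do.call(rbind, extra))
  }
  sph
}

# Fluence factor at depth below the phantom's top surface (z of highest
# structure), exponential decay model exp(-k * depth_cm).
fluence_at <- function(ph, z, z_top) {
  if (ph$fluence_decay <= 0) return(rep(1, length(z)))
  depth_cm <- pmax(0, z_top - z) / 10
  exp(-ph$fluence_decay * depth_cm)
}

#' Simulate a full rotational scan of a phantom
#'
#' Superposes the analytic N-wave of every phantom structure (cylinders are
#' discretized into overlapping spheres) at every virtual element pose,
#' applies the transducer band-pass response, and adds seeded white Gaussian
#' noise. Amplitudes are proportional to `mu_a` times the local fluence.
#'
#' @param phantom A `pact_phantom`.
#' @param matrix A `pact_detmat` detection matrix.
#' @param response A `pact_response` (NULL to skip filtering).
#' @param c Speed of sound, mm/us.
#' @param noise_sd Additive Gaussian noise SD (pressure units).
#' @param seed Integer RNG seed (determinism of the noise).
#' @param t0 Start of the recording window, us.
#' @param n_samples Number of time samples per trace; default covers the
#'   farthest structure-element distance.
#' @param sampling_rate MHz.
#' @return A `pact_sinogram` with `traces` (S x N x T), `sampling_rate`,
#'   `t0`, the detection `matrix` and provenance metadata.
#' @export
simulate_scan <- function(phantom, matrix, response = transducer_response(),
                          c = 1.5, noise_sd = 0, seed = 1L, t0 = NULL,
                          n_samples = NULL, sampling_rate = 40) {
  stopifnot(inherits(phantom, "pact_phantom"), inherits(matrix, "pact_detmat"))
  if (c <= 0) stop("'c' must be positive", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative", call. = FALSE)
  sph <- phantom_as_spheres(phantom)
  S <- dim(matrix$positions)[1]; N <- dim(matrix$positions)[2]
  R <- sqrt(sum(matrix$positions[1, 1, ]^2))
  if (is.null(t0) || is.null(n_samples)) {
    if (nrow(sph)) {
      ctr <- as.matrix(sph[, c("x", "y", "z")])
      dmax <- max(sqrt(rowSums(ctr^2))) + max(sph$radius)
    } else dmax <- 0
    rng <- c(max(0, (R - dmax) / c - 1), (R + dmax) / c + 1)
    if (is.null(t0)) t0 <- floor(rng[1] * sampling_rate) / sampling_rate
    if (is.null(n_samples))
      n_samples <- ceiling((rng[2] - t0) * sampling_rate) + 1L
  }
  t_grid <- t0 + (seq_len(n_samples) - 1L) / sampling_rate
  z_top <- if (nrow(sph)) max(sph$z + sph$radius) else 0
  traces <- array(0, c(S, N, n_samples))
  if (nrow(sph)) {
    amps <- sph$mu_a * fluence_at(phantom, sph$z, z_top)
    for (s in seq_len(S)) {
      pos <- matrix$positions[s, , , drop = TRUE]
      if (is.null(dim(pos))) pos <- matrix(pos, 1, 3)
      acc <- matrix(0, N, n_samples)
      for (i in seq_len(nrow(sph))) {
        d <- sqrt((pos[, 1] - sph$x[i])^2 + (pos[, 2] - sph$y[i])^2 +
                  (pos[, 3] - sph$z[i])^2)
        if (any(d <= sph$radius[i]))
          stop("a detector pose lies inside a phantom structure",
               call. = FALSE)
        # u[n, t] = d_n - c t ; N-wave support |u| < radius
        u <- outer(d, c * t_grid, "-")
        on <- abs(u) < sph$radius[i]
        if (any(on)) {
          contrib <- matrix(0, N, n_samples)
          contrib[on] <- (amps[i] * u / (2 * d))[on]
          acc <- acc + contrib
        }
      }
      if (!is.null(response))
        acc <- t(apply_transducer_response(t(acc), response, sampling_rate))
      traces[s, , ] <- acc
    }
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    traces <- traces + stats::rnorm(length(traces), sd = noise_sd)
  }
  structure(list(traces = traces, sampling_rate = sampling_rate, t0 = t0,
                 c = c, matrix = matrix,
                 meta = list(seed = as.integer(seed), noise_sd = noise_sd,
                             n_structures = nrow(sph))),
            class = "pact_sinogram")
}

#' Simulate a point-source calibration session
#'
#' Records the traces of a small point absorber placed at several positions,
#' as used by the time-of-flight geometric self-calibration. Ground-truth
#' times of flight (|source - element| / c, from the possibly perturbed
#' static geometry) are retained for testing.
#'
#' @param source_positions M x 3 matrix of source positions, mm.
#' @param geom Static `pact_geometry` (calibration uses the unrotated array,
#'   all elements sharing the scan rotation axis).
#' @param response A `pact_response` or NULL.
#' @param c Speed of sound, mm/us.
#' @param jitter SD of Gaussian perturbation added to the true times of
#'   flight, us (0 = exact).
#' @param source_radius Physical radius of the point absorber, mm.
#' @param seed RNG seed for the jitter.
#' @param sampling_rate MHz.
#' @return A `pact_pointsource_session` with `tof` (M x N true times, us,
#'   jittered if requested), `tof_true`, traces per source (list of N x T
#'   matrices), `t_grid`, geometry and settings.
#' @export
make_point_source_session <- function(source_positions, geom,
                                      response = transducer_response(),
                                      c = 1.5, jitter = 0,
                                      source_radius = 0.05, seed = 1L,
                                      sampling_rate = 40) {
  src <- matrix(source_positions, ncol = 3)
  stopifnot(nrow(src) >= 1, inherits(geom, "pact_geometry"))
  R <- max(sqrt(rowSums(geom$positions^2)))
  if (any(sqrt(rowSums(src^2)) > R))
    warning("point source outside the hemisphere radius; flagged, allowed")
  M <- nrow(src); N <- nrow(geom$positions)
  tof <- matrix(0, M, N)
  for (m in seq_len(M))
    tof[m, ] <- sqrt(colSums((t(geom$positions) - src[m, ])^2)) / c
  tof_true <- tof
  if (jitter > 0) {
    set.seed(as.integer(seed))
    tof <- tof + matrix(stats::rnorm(M * N, sd = jitter), M, N)
  }
  t0 <- max(0, floor((min(tof) - 1) * sampling_rate) / sampling_rate)
  n_samples <- ceiling((max(tof) + 1 - t0) * sampling_rate) + 1L
  t_grid <- t0 + (seq_len(n_samples) - 1L) / sampling_rate
  traces <- lapply(seq_len(M), function(m) {
    tr <- sapply(seq_len(N), function(n)
      sphere_signal(src[m, ], source_radius, 1, geom$positions[n, ],
                    t_grid, c))
    tr <- if (!is.null(response))
      apply_transducer_response(tr, response, sampling_rate) else tr
    t(tr)  # N x T
  })
  structure(list(tof = tof, tof_true = tof_true, traces = traces,
                 t_grid = t_grid, t0 = t0, sampling_rate = sampling_rate,
                 geometry = geom, source_positions = src, c = c,
                 source_radius = source_radius),
            class = "pact_pointsource_session")
}

#' Breast-mimicking and vessel phantom presets
#'
#' `make_breast_phantom()`: hemispherical breast-mimicking background
#' (absorption 0.05 cm^-1) with tumor spheres of absorption 0.105 cm^-1
#' (2.1 times background) embedded at 2 cm depth, with diameters from 1 mm
#' up; optional exponential fluence decay of 0.9 cm^-1.
#' `make_vessel_phantom()`: branching cylinders with diameters from 0.4 to
#' 2 mm for vesselness / post-processing tests.
#'
#' @param preset Preset name: `"breast"` or `"breast-uniform-fluence"` for
#'   [make_breast_phantom()]; `"branching"` for [make_vessel_phantom()].
#' @return A `pact_phantom`.
#' @export
make_breast_phantom <- function(preset = "breast") {
  presets <- c("breast", "breast-uniform-fluence")
  if (!preset %in% presets)
    stop("unknown preset '", preset, "'; available: ",
         paste(presets, collapse = ", "), call. = FALSE)
  surface_z <- 40  # top of the breast dome, mm above hemisphere center
  depth <- 20      # tumors embedded at 2 cm depth
  diam <- c(1, 2, 4, 8)
  sph <- data.frame(
    x = c(0, 10, -10, 0), y = c(0, 0, 0, -12),
    z = surface_z - depth, radius = diam / 2, mu_a = 0.105)
  ph <- phantom(spheres = sph, background_mu_a = 0.05,
                reduced_scattering = 5,
                fluence_decay = if (preset == "breast") 0.9 else 0)
  ph$surface_z <- surface_z
  ph
}

#' @rdname make_breast_phantom
#' @export
make_vessel_phantom <- function(preset = "branching") {
  if (!identical(preset, "branching"))
    stop("unknown preset '", preset, "'; available: branching",
         call. = FALSE)
  trunk <- data.frame(x1 = -8, y1 = 0, z1 = 10, x2 = 8, y2 = 0, z2 = 10,
                      radius = 1, mu_a = 1)
  branch1 <- data.frame(x1 = 0, y1 = 0, z1 = 10, x2 = 6, y2 = 6, z2 = 14,
                        radius = 0.5, mu_a = 1)
  branch2 <- data.frame(x1 = 0, y1 = 0, z1 = 10, x2 = -5, y2 = 6, z2 = 13,
                        radius = 0.2, mu_a = 1)  # 0.4-mm-diameter vessel
  phantom(cylinders = rbind(trunk, branch1, branch2), background_mu_a = 0)
}
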
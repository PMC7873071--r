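#' System configuration for the hemispherical detection geometry
#'
#' Describes the four-arc hemispherical transducer array and its coaxial
#' rotational scan. Defaults correspond to a 1024-element system: four
#' 83-degree arcs of 256 elements each on a 130-mm-radius hemisphere,
#' 2.25 MHz center frequency, 40 MHz sampling, 10 Hz laser repetition rate,
#' and a 90-degree scan span.
#'
#' The coordinate frame is right-handed with the origin at the hemisphere
#' center, +Z pointing up toward the imaging platform, and the scan rotation
#' about +Z. All elements sit at Z <= 0. Each arc lies in a plane containing
#' the Z axis; elements are uniformly spaced in elevation angle, spanning
#' `arc_span` degrees up to `arc_elevation_top` (default: -83 to 0 degrees,
#' i.e. the shallowest element at the equator and a 7-degree polar gap so
#' the four arcs clear each other at the pole).
#'
#' @param hemisphere_radius Hemisphere radius in mm.
#' @param arc_span Angular span of each arc in degrees (< 180).
#' @param elements_per_arc Number of elements on each arc.
#' @param n_arcs Number of arcs, equally spaced in azimuth.
#' @param element_pitch Nominal element pitch in mm (metadata).
#' @param element_aperture Element aperture (width, height) in mm.
#' @param center_frequency Transducer center frequency in MHz.
#' @param fractional_bandwidth_one_way One-way fractional bandwidth.
#' @param sampling_rate DAQ sampling rate in MHz.
#' @param laser_rep_rate Laser pulse repetition rate in Hz.
#' @param scan_span Total rotational scan span in degrees, in (0, 360].
#' @param arc_elevation_top Elevation (degrees, negative below the equator) of
#'   the shallowest element of each arc; the arc extends `arc_span` degrees
#'   below it.
#' @return An object of class `pact_config`.
#' @export
system_config <- function(hemisphere_radius = 130,
                          arc_span = 83,
                          elements_per_arc = 256,
                          n_arcs = 4,
                          element_pitch = 0.74,
                          element_aperture = c(0.6, 0.7),
                          center_frequency = 2.25,
                          fractional_bandwidth_one_way = 0.98,
                          sampling_rate = 40,
                          laser_rep_rate = 10,
                          scan_span = 90,
                          arc_elevation_top = 0) {
  chk_pos <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("'%s' must be a single positive finite number", name),
           call. = FALSE)
  }
  chk_pos(hemisphere_radius, "hemisphere_radius")
  chk_pos(arc_span, "arc_span")
  chk_pos(center_frequency, "center_frequency")
  chk_pos(sampling_rate, "sampling_rate")
  chk_pos(laser_rep_rate, "laser_rep_rate")
  chk_pos(element_pitch, "element_pitch")
  if (arc_span >= 180) stop("'arc_span' must be < 180 degrees", call. = FALSE)
  if (!is.numeric(scan_span) || scan_span <= 0 || scan_span > 360)
    stop("'scan_span' must be in (0, 360] degrees", call. = FALSE)
  if (elements_per_arc < 1 || elements_per_arc != round(elements_per_arc))
    stop("'elements_per_arc' must be a positive integer", call. = FALSE)
  if (n_arcs < 1 || n_arcs != round(n_arcs))
    stop("'n_arcs' must be a positive integer", call. = FALSE)
  structure(list(
    hemisphere_radius = hemisphere_radius,
    arc_span = arc_span,
    elements_per_arc = as.integer(elements_per_arc),
    n_arcs = as.integer(n_arcs),
    element_pitch = element_pitch,
    element_aperture = element_aperture,
    center_frequency = center_frequency,
    fractional_bandwidth_one_way = fractional_bandwidth_one_way,
    sampling_rate = sampling_rate,
    laser_rep_rate = laser_rep_rate,
    scan_span = scan_span,
    arc_elevation_top = arc_elevation_top
  ), class = "pact_config")
}

#' @export
print.pact_config <- function(x, ...) {
  cat(sprintf(
    "3D-PACT system: %d arcs x %d elements (%d total), R = %g mm\n",
    x$n_arcs, x$elements_per_arc, x$n_arcs * x$elements_per_arc,
    x$hemisphere_radius))
  cat(sprintf("  arc span %g deg (top elevation %g deg), scan span %g deg\n",
              x$arc_span, x$arc_elevation_top, x$scan_span))
  cat(sprintf("  fc = %g MHz, fs = %g MHz, PRF = %g Hz\n",
              x$center_frequency, x$sampling_rate, x$laser_rep_rate))
  invisible(x)
}

#' Build the nominal (uncalibrated) element geometry
#'
#' Places `n_arcs` arcs of `elements_per_arc` elements each on the hemisphere.
#' Arcs are equally spaced in azimuth (90 degrees apart for the default four
#' arcs); elements are uniformly spaced in elevation along each arc. Element
#' ordering is arc-major, then along-arc from the deepest element (near the
#' pole) upward. Normals are unit vectors pointing at the origin.
#'
#' @param config A `pact_config` from [system_config()].
#' @return A `pact_geometry` list with `positions` (N x 3, mm), `normals`
#'   (N x 3, unit), `element_ids` (integer), `arc_index` (integer, 1-based),
#'   and the originating `config`.
#' @export
build_nominal_array <- function(config) {
  stopifnot(inherits(config, "pact_config"))
  R <- config$hemisphere_radius
  npa <- config$elements_per_arc
  na <- config$n_arcs
  elev_top <- config$arc_elevation_top * pi / 180
  span <- config$arc_span * pi / 180
  if (npa == 1L) {
    elevs <- elev_top - span  # single element at the arc's deep reference pole
  } else {
    elevs <- seq(elev_top - span, elev_top, length.out = npa)
  }
  azims <- (seq_len(na) - 1L) * 2 * pi / na
  n_total <- npa * na
  pos <- matrix(0, n_total, 3)
  arc_index <- integer(n_total)
  k <- 1L
  for (a in seq_len(na)) {
    ce <- cos(elevs); se <- sin(elevs)
    pos[k:(k + npa - 1L), ] <- R * cbind(ce * cos(azims[a]),
                                         ce * sin(azims[a]),
                                         se)
    arc_index[k:(k + npa - 1L)] <- a
    k <- k + npa
  }
  if (any(pos[, 3] > 1e-9))
    stop("arc placement puts elements above the equator; ",
         "check 'arc_elevation_top' and 'arc_span'", call. = FALSE)
  normals <- -pos / sqrt(rowSums(pos^2))
  structure(list(positions = pos, normals = normals,
                 element_ids = seq_len(n_total), arc_index = arc_index,
                 config = config),
            class = "pact_geometry")
}

#' Rotate an element geometry about the vertical scan axis
#'
#' Rigid rotation about +Z; per-element radii and elevations are preserved.
#'
#' @param geom A `pact_geometry`.
#' @param angle Rotation angle in radians (counterclockwise seen from +Z).
#' @return The rotated `pact_geometry`.
#' @export
rotate_elements <- function(geom, angle) {
  stopifnot(inherits(geom, "pact_geometry"), is.finite(angle))
  if (angle == 0) return(geom)
  ca <- cos(angle); sa <- sin(angle)
  Rz <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  geom$positions <- geom$positions %*% t(Rz)
  geom$normals <- geom$normals %*% t(Rz)
  geom
}

#' Scan trajectory of the coaxial rotation
#'
#' Laser firings are spaced at the repetition rate starting at t = 0; the
#' number of firings over a scan of `duration` seconds is
#' `floor(duration * laser_rep_rate) + 1`. Rotation angle at each firing is
#' `angular_speed * time`.
#'
#' @param angular_speed Rotation speed in rad/s (system presets: pi/4 for
#'   0.5-Hz functional imaging, pi/10 for 5-s anatomy, pi/20 for 10-s scans).
#' @param duration Scan duration in seconds.
#' @param laser_rep_rate Laser repetition rate in Hz.
#' @param scan_span Maximum allowed rotation in degrees.
#' @return A `pact_trajectory` with `firing_times` (s) and `rotation_angles`
#'   (rad).
#' @export
scan_trajectory <- function(angular_speed, duration, laser_rep_rate = 10,
                            scan_span = 90) {
  if (!is.numeric(duration) || duration <= 0)
    stop("'duration' must be positive", call. = FALSE)
  firing_times <- seq(0L, floor(duration * laser_rep_rate)) / laser_rep_rate
  rotation_angles <- angular_speed * firing_times
  if (max(rotation_angles) > scan_span * pi / 180 + 1e-12)
    stop(sprintf("trajectory exceeds scan span: %.3f deg > %g deg",
                 max(rotation_angles) * 180 / pi, scan_span), call. = FALSE)
  structure(list(angular_speed = angular_speed, duration = duration,
                 laser_rep_rate = laser_rep_rate,
                 firing_times = firing_times,
                 rotation_angles = rotation_angles),
            class = "pact_trajectory")
}

#' Sweep a geometry through a trajectory into a detection matrix
#'
#' Each laser firing sees the physical array rotated to that firing's angle;
#' the union of element poses over all firings forms the densely sampled
#' virtual hemispherical detection matrix.
#'
#' @param geom A `pact_geometry`.
#' @param traj A `pact_trajectory`.
#' @return A `pact_detmat` with `positions` (S x N x 3 mm), `normals`
#'   (S x N x 3), `firing_times` (s), and the static `geometry`.
#' @export
make_detection_matrix <- function(geom, traj) {
  stopifnot(inherits(geom, "pact_geometry"), inherits(traj, "pact_trajectory"))
  S <- length(traj$firing_times)
  N <- nrow(geom$positions)
  pos <- array(0, c(S, N, 3))
  nrm <- array(0, c(S, N, 3))
  for (s in seq_len(S)) {
    g <- rotate_elements(geom, traj$rotation_angles[s])
    pos[s, , ] <- g$positions
    nrm[s, , ] <- g$normals
  }
  structure(list(positions = pos, normals = nrm,
                 firing_times = traj$firing_times,
                 rotation_angles = traj$rotation_angles,
                 geometry = geom),
            class = "pact_detmat")
}

#' Apply per-element radial calibration factors
#'
#' Scales each element position by its factor `alpha[n]` about the origin,
#' moving it along the radial axis; normals are unchanged. This is how the
#' radial manufacturing defects recovered by calibration are imposed on (or
#' removed from) a geometry.
#'
#' @param geom A `pact_geometry`.
#' @param alpha Numeric vector of positive radial factors, one per element.
#' @return The scaled `pact_geometry` (with an `alpha` field recording the
#'   applied factors).
#' @export
apply_radial_factors <- function(geom, alpha) {
  stopifnot(inherits(geom, "pact_geometry"))
  n <- nrow(geom$positions)
  if (length(alpha) != n)
    stop(sprintf("'alpha' must have length %d (one per element)", n),
         call. = FALSE)
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("all radial factors must be positive and finite", call. = FALSE)
  geom$positions <- geom$positions * alpha
  geom$alpha <- if (is.null(geom$alpha)) alpha else geom$alpha * alpha
  geom
}

# Flatten an S x N x 3 detection matrix to (S*N) x 3 pose list (firing-major).
flatten_detmat <- function(matrix) {
  S <- dim(matrix$positions)[1]; N <- dim(matrix$positions)[2]
  pos <- matrix(aperm(matrix$positions, c(2, 1, 3)), S * N, 3)
  nrm <- matrix(aperm(matrix$normals, c(2, 1, 3)), S * N, 3)
  list(positions = pos, normals = nrm, S = S, N = N)
}
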
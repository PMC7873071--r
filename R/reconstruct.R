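#' Reconstruction volume grid
#'
#' Axis-aligned voxel grid in the system frame. `origin` is the center of
#' voxel (1, 1, 1); voxel centers are `origin + (index - 1) * voxel_size`.
#'
#' @param shape Integer length-3 voxel counts (nx, ny, nz).
#' @param voxel_size Isotropic voxel size in mm (default 0.13).
#' @param origin Length-3 center of the first voxel, mm. Default centers the
#'   grid on the origin of the system frame.
#' @param values Optional array of voxel values (dim = shape).
#' @return A `pact_volume`.
#' @export
volume_grid <- function(shape, voxel_size = 0.13, origin = NULL,
                        values = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (voxel_size <= 0) stop("'voxel_size' must be positive", call. = FALSE)
  if (is.null(origin)) origin <- -(shape - 1) / 2 * voxel_size
  if (is.null(values)) values <- array(0, shape)
  stopifnot(all(dim(values) == shape))
  structure(list(values = values, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "pact_volume")
}

#' @export
print.pact_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("volume: %d x %d x %d voxels at %g mm, origin (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$voxel_size,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

# Voxel center coordinates along each axis.
grid_axes <- function(grid) {
  d <- dim(grid$values)
  lapply(1:3, function(a) grid$origin[a] + (seq_len(d[a]) - 1) *
           grid$voxel_size)
}

#' Axis-aligned half-ellipsoid tissue surface
#'
#' The holding-cup / tissue boundary: an ellipsoid centered on the scan axis
#' at height `center_z`, semi-axes `(a, b, c_z)`, of which the lower half
#' (z <= center_z) bounds the tissue. Points strictly inside the lower half
#' are "tissue"; everything else is coupling fluid.
#'
#' @param semi_axes Length-3 positive semi-axes (a, b, c_z), mm.
#' @param center_z Height of the ellipsoid center on the scan axis, mm.
#' @return A `pact_ellipsoid`.
#' @export
ellipsoid_surface <- function(semi_axes, center_z = 0) {
  stopifnot(length(semi_axes) == 3)
  if (any(semi_axes <= 0)) stop("semi-axes must be positive", call. = FALSE)
  structure(list(semi_axes = as.numeric(semi_axes),
                 center_z = as.numeric(center_z)),
            class = "pact_ellipsoid")
}

#' Test whether points are inside the tissue half-ellipsoid
#'
#' @param surface A `pact_ellipsoid`.
#' @param points N x 3 matrix of coordinates, mm.
#' @return Logical vector.
#' @export
ellipsoid_inside <- function(surface, points) {
  p <- matrix(points, ncol = 3)
  q <- (p[, 1] / surface$semi_axes[1])^2 +
       (p[, 2] / surface$semi_axes[2])^2 +
       ((p[, 3] - surface$center_z) / surface$semi_axes[3])^2
  q <= 1 & p[, 3] <= surface$center_z
}

#' Speed-of-sound model for reconstruction
#'
#' Single speed (no surface) or dual speed: tissue speed inside the fitted
#' half ellipsoid, coupling-fluid speed outside.
#'
#' @param c_water Speed of sound in the coupling fluid, mm/us.
#' @param c_tissue Speed of sound in tissue, mm/us (default: equal to
#'   `c_water`).
#' @param surface A `pact_ellipsoid`, or NULL for single-speed.
#' @return A `pact_speed_model`.
#' @export
speed_model <- function(c_water = 1.5, c_tissue = c_water, surface = NULL) {
  for (v in c(c_water, c_tissue)) {
    if (v <= 0) stop("speeds of sound must be positive", call. = FALSE)
    if (v < 1.3 || v > 1.7)
      warning(sprintf("speed of sound %.3f mm/us outside the usual ",
                      v), "[1.3, 1.7] range", call. = FALSE)
  }
  if (!is.null(surface)) stopifnot(inherits(surface, "pact_ellipsoid"))
  structure(list(c_water = c_water, c_tissue = c_tissue, surface = surface),
            class = "pact_speed_model")
}

#' Two-segment straight-ray delay through the tissue ellipsoid
#'
#' Exact quadratic ray-ellipsoid intersection clipped to the lower
#' half-space splits the voxel-element ray into tissue and coupling-fluid
#' segments; the delay is `L_tissue / c_tissue + L_water / c_water`. With
#' equal speeds this reduces to `|voxel - element| / c`.
#'
#' @param voxel N x 3 (or length-3) voxel coordinates, mm.
#' @param element N x 3 (or length-3) element coordinates, mm.
#' @param speed A `pact_speed_model` with a surface (unless speeds are
#'   equal).
#' @return Delay(s) in us.
#' @export
dual_sos_delay <- function(voxel, element, speed) {
  stopifnot(inherits(speed, "pact_speed_model"))
  v <- matrix(voxel, ncol = 3)
  e <- matrix(element, ncol = 3)
  if (nrow(e) == 1 && nrow(v) > 1) e <- e[rep(1, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1 && nrow(e) > 1) v <- v[rep(1, nrow(e)), , drop = FALSE]
  len <- sqrt(rowSums((v - e)^2))
  if (any(len == 0))
    stop("zero-length voxel-element ray", call. = FALSE)
  if (is.null(speed$surface)) return(len / speed$c_water)
  s <- speed$surface
  .dual_delay_cpp(v, e, s$semi_axes[1], s$semi_axes[2], s$semi_axes[3],
                  s$center_z, speed$c_tissue, speed$c_water)
}

# UBP filtered term b(t) = 2 p(t) - 2 t dp/dt, central differences in time.
# traces: T x P matrix; t_grid in us. Returns T x P.
ubp_filter_term <- function(traces, t_grid) {
  T <- nrow(traces)
  dt <- t_grid[2] - t_grid[1]
  dp <- traces
  if (T >= 3) {
    dp[2:(T - 1), ] <- (traces[3:T, , drop = FALSE] -
                        traces[1:(T - 2), , drop = FALSE]) / (2 * dt)
    dp[1, ] <- (traces[2, ] - traces[1, ]) / dt
    dp[T, ] <- (traces[T, ] - traces[T - 1, ]) / dt
  } else {
    dp[] <- 0
  }
  2 * traces - 2 * t_grid * dp
}

# Sinogram traces as a T x (S*N) matrix, pose-major order matching
# flatten_detmat().
sinogram_trace_matrix <- function(sinogram) {
  tr <- sinogram$traces
  S <- dim(tr)[1]; N <- dim(tr)[2]; T <- dim(tr)[3]
  matrix(aperm(tr, c(3, 2, 1)), T, S * N)
}

#' Universal back-projection reconstruction
#'
#' Back-projects the filtered term `b(t) = 2 p(t) - 2 t dp/dt` of every
#' trace onto the voxel grid at the delay given by the speed model (single
#' speed: `|r - r_e| / c`; dual speed: two-segment ellipsoid delays),
#' accumulating with solid-angle weights (cos(theta) / d^2, normalized per
#' voxel). Linear in the input sinogram. Delays falling outside the recorded
#' window are skipped and counted in the `skipped` attribute of the result.
#'
#' @param sinogram A `pact_sinogram`.
#' @param grid A `pact_volume` defining the reconstruction grid.
#' @param speed A `pact_speed_model` (default: single speed, the sinogram's
#'   simulation speed if recorded, else 1.5 mm/us).
#' @param matrix Detection matrix; defaults to the sinogram's.
#' @param interpolation `"linear"` (default) or `"nearest"` delay lookup.
#' @param area_weights Weight each virtual pose by the detection-surface
#'   area it represents (proportional to the cosine of its elevation, the
#'   azimuthal arc length swept per firing). The rotational scan crowds
#'   poses together near the pole; without this quadrature factor the polar
#'   direction is overweighted and the point-spread function sharpens along
#'   Z at the expense of X-Y isotropy. Default TRUE.
#' @return The grid with reconstructed `values` (class `pact_volume`).
#' @export
ubp_backproject <- function(sinogram, grid, speed = NULL,
                            matrix = sinogram$matrix,
                            interpolation = c("linear", "nearest"),
                            area_weights = TRUE) {
  stopifnot(inherits(sinogram, "pact_sinogram"),
            inherits(grid, "pact_volume"))
  interpolation <- match.arg(interpolation)
  if (is.null(speed))
    speed <- speed_model(if (!is.null(sinogram$c)) sinogram$c else 1.5)
  fl <- flatten_detmat(matrix)
  pose_w <- if (area_weights) {
    elev_cos <- sqrt(pmax(0, 1 - (fl$positions[, 3] /
      sqrt(rowSums(fl$positions^2)))^2))
    pmax(elev_cos, 1e-6)
  } else numeric(0)
  T <- dim(sinogram$traces)[3]
  t_grid <- sinogram$t0 + (seq_len(T) - 1) / sinogram$sampling_rate
  bmat <- ubp_filter_term(sinogram_trace_matrix(sinogram), t_grid)
  ell <- if (!is.null(speed$surface))
    c(speed$surface$semi_axes, speed$surface$center_z) else numeric(0)
  vals <- .ubp_core(bmat, fl$positions, fl$normals,
                    dim(grid$values), grid$origin, grid$voxel_size,
                    sinogram$t0, 1 / sinogram$sampling_rate,
                    speed$c_water, speed$c_tissue, ell,
                    interpolation == "linear", pose_w)
  skipped <- attr(vals, "skipped")
  grid$values <- array(as.numeric(vals), dim(grid$values))
  attr(grid, "skipped") <- skipped
  grid
}

#' Distance-dependent antialiasing of a sinogram
#'
#' Mitigates spatial undersampling artefacts outside the well-resolved
#' field of view: channels are upsampled 2x by linear interpolation along
#' the element index within each arc, and every trace is low-pass filtered
#' at the cutoff for the most distant-from-axis voxel it serves,
#' `f_cut(d) = min(f_max, f_max * d0 / d)`, where `d0` is the well-resolved
#' FOV radius. At `d = 0` the filter passes the full system band.
#'
#' @param sinogram A `pact_sinogram`.
#' @param grid_extent Maximum distance from the scan axis served by the
#'   reconstruction grid, mm (a `pact_volume` may be given instead).
#' @param f_max Full system bandwidth edge, MHz; defaults to
#'   `center_frequency * (1 + fractional_bandwidth)` of the matrix config
#'   if available, else 2.25 * 1.98.
#' @param d0 Well-resolved FOV radius, mm (default 10: the ~2-cm FOV of a
#'   5-s scan).
#' @param upsample Insert interpolated midpoint channels within each arc.
#' @return The filtered `pact_sinogram` (with an enlarged detection matrix
#'   when `upsample = TRUE`); the applied cutoff is recorded in
#'   `meta$f_cut_MHz`.
#' @export
antialias_filter <- function(sinogram, grid_extent, f_max = NULL, d0 = 10,
                             upsample = TRUE) {
  stopifnot(inherits(sinogram, "pact_sinogram"))
  if (inherits(grid_extent, "pact_volume")) {
    ax <- grid_axes(grid_extent)
    grid_extent <- sqrt(max(ax[[1]]^2) + max(ax[[2]]^2))
  }
  cfg <- sinogram$matrix$geometry$config
  if (is.null(f_max))
    f_max <- if (!is.null(cfg))
      cfg$center_frequency * (1 + cfg$fractional_bandwidth_one_way)
    else 2.25 * 1.98
  d <- max(grid_extent, 0)
  f_cut <- if (d <= d0) f_max else f_max * d0 / d
  out <- sinogram
  if (upsample) {
    tr <- sinogram$traces
    S <- dim(tr)[1]; N <- dim(tr)[2]; T <- dim(tr)[3]
    geom <- sinogram$matrix$geometry
    arcs <- geom$arc_index
    new_order <- list(); new_pos <- list(); new_arc <- integer()
    # per arc: originals interleaved with midpoints
    for (a in unique(arcs)) {
      idx <- which(arcs == a)
      n <- length(idx)
      if (n == 1) { ord <- rbind(c(idx, idx, 1)) } else {
        ord <- matrix(0, 2 * n - 1, 3)
        ord[seq(1, 2 * n - 1, by = 2), ] <- cbind(idx, idx, 1)
        ord[seq(2, 2 * n - 2, by = 2), ] <- cbind(idx[-n], idx[-1], 0.5)
      }
      new_order[[length(new_order) + 1]] <- ord
      new_arc <- c(new_arc, rep(a, nrow(ord)))
    }
    ord <- do.call(rbind, new_order)
    N2 <- nrow(ord)
    # interpolated static positions, re-projected to the sphere radius
    p1 <- geom$positions[ord[, 1], , drop = FALSE]
    p2 <- geom$positions[ord[, 2], , drop = FALSE]
    pm <- ord[, 3] * p1 + (1 - ord[, 3]) * p2
    r1 <- sqrt(rowSums(p1^2))
    pm <- pm / sqrt(rowSums(pm^2)) * r1
    geom2 <- geom
    geom2$positions <- pm
    geom2$normals <- -pm / sqrt(rowSums(pm^2))
    geom2$element_ids <- seq_len(N2)
    geom2$arc_index <- new_arc
    geom2$alpha <- NULL
    traj <- structure(list(
      firing_times = sinogram$matrix$firing_times,
      rotation_angles = sinogram$matrix$rotation_angles),
      class = "pact_trajectory")
    out$matrix <- make_detection_matrix(geom2, traj)
    tr2 <- array(0, c(S, N2, T))
    for (s in seq_len(S))
      tr2[s, , ] <- ord[, 3] * tr[s, ord[, 1], , drop = TRUE] +
        (1 - ord[, 3]) * tr[s, ord[, 2], , drop = TRUE]
    out$traces <- tr2
    out$meta$original_channels <- which(ord[, 1] == ord[, 2])
  }
  if (f_cut < f_max - 1e-12) {
    T <- dim(out$traces)[3]
    f <- c(seq(0, floor(T / 2)), seq(-ceiling(T / 2) + 1, -1)) *
      out$sampling_rate / T
    # raised-cosine rolloff over 20% of the cutoff
    roll <- 0.2 * f_cut
    af <- abs(f)
    g <- ifelse(af <= f_cut - roll, 1,
                ifelse(af >= f_cut + roll, 0,
                       0.5 * (1 + cos(pi * (af - f_cut + roll) /
                                      (2 * roll)))))
    S <- dim(out$traces)[1]
    for (s in seq_len(S)) {
      x <- t(out$traces[s, , , drop = TRUE])
      if (is.null(dim(x))) x <- matrix(x, ncol = 1)
      out$traces[s, , ] <- t(Re(stats::mvfft(stats::mvfft(x) * g,
                                             inverse = TRUE)) / T)
    }
  }
  out$meta$f_cut_MHz <- f_cut
  out$meta$antialias_d_mm <- d
  out
}

#' Antialiasing cutoff law
#'
#' @param d Distance from the scan axis, mm.
#' @param f_max Full band edge, MHz.
#' @param d0 Well-resolved FOV radius, mm.
#' @return Cutoff frequency in MHz, nonincreasing in `d`.
#' @export
antialias_cutoff <- function(d, f_max = 2.25 * 1.98, d0 = 10) {
  ifelse(d <= d0, f_max, f_max * d0 / d)
}

#' Extract the tissue surface from an initial reconstruction
#'
#' Marches detection windows along rays toward the tissue — horizontally
#' inward toward the scan axis at every height, and vertically downward from
#' the top face — and marks the first window whose mean amplitude exceeds
#' the background mean plus `k` background standard deviations. Background
#' statistics come from the outer 10 percent shell of the volume.
#'
#' @param volume A `pact_volume` (initial single-speed reconstruction).
#' @param n_azimuth Number of horizontal ray directions per height.
#' @param window Detection window length in voxels (default 5).
#' @param k Threshold in background SDs (default 3).
#' @param max_failure_fraction Error if more than this fraction of rays
#'   finds no crossing (default 0.5).
#' @return Data frame of surface points (`x, y, z`, mm) with per-ray
#'   `confidence` (window mean minus background mean, in background SDs;
#'   `Inf` when the background SD is zero).
#' @export
extract_surface <- function(volume, n_azimuth = 16, window = 5, k = 3,
                            max_failure_fraction = 0.5) {
  stopifnot(inherits(volume, "pact_volume"))
  vals <- volume$values
  d <- dim(vals)
  ax <- grid_axes(volume)
  # background: the x-y corner regions outside the inscribed circle, which
  # a centered tissue volume cannot reach; fall back to the outer 10% band
  r_in <- 0.98 * min(max(abs(ax[[1]])), max(abs(ax[[2]])))
  rxy <- sqrt(outer(ax[[1]]^2, ax[[2]]^2, "+"))
  corner <- rxy > r_in
  if (sum(corner) >= 8) {
    shell <- vals[array(corner, d)]
  } else {
    nb <- pmax(1L, floor(d[1:2] * 0.1))
    shell <- c(vals[c(seq_len(nb[1]), d[1] - seq_len(nb[1]) + 1L), , ],
               vals[, c(seq_len(nb[2]), d[2] - seq_len(nb[2]) + 1L), ])
  }
  bg_mean <- mean(shell); bg_sd <- stats::sd(shell)
  thr <- bg_mean + k * bg_sd + 1e-9 * max(abs(vals))
  step <- volume$voxel_size
  nearest <- function(x, axis) {
    i <- round((x - volume$origin[axis]) / step) + 1
    pmin(pmax(i, 1), d[axis])
  }
  sample_ray <- function(start, dir, n_steps) {
    tt <- (seq_len(n_steps) - 1) * step
    px <- start[1] + tt * dir[1]
    py <- start[2] + tt * dir[2]
    pz <- start[3] + tt * dir[3]
    v <- vals[cbind(nearest(px, 1), nearest(py, 2), nearest(pz, 3))]
    list(v = v, px = px, py = py, pz = pz)
  }
  hits <- list(); n_rays <- 0L; n_found <- 0L
  scan_one <- function(start, dir, n_steps) {
    ray <- sample_ray(start, dir, n_steps)
    if (length(ray$v) < window) return(NULL)
    wm <- stats::filter(ray$v, rep(1 / window, window), sides = 1)
    hit <- which(!is.na(wm) & wm > thr)[1]
    # require a clean background prefix: rays starting inside tissue are
    # unreliable and are dropped
    if (is.na(hit) || hit <= window) return(NULL)
    ctr <- hit  # the sample whose arrival pushed the window over threshold
    conf <- if (bg_sd > 0) (wm[hit] - bg_mean) / bg_sd else Inf
    data.frame(x = start[1] + (ctr - 1) * step * dir[1],
               y = start[2] + (ctr - 1) * step * dir[2],
               z = start[3] + (ctr - 1) * step * dir[3],
               confidence = conf)
  }
  # horizontal rays, every other height
  r_start <- sqrt(max(ax[[1]]^2) + max(ax[[2]]^2))
  for (kz in seq(1, d[3], by = 2)) {
    z <- ax[[3]][kz]
    for (phi in (seq_len(n_azimuth) - 1) * 2 * pi / n_azimuth) {
      dir <- c(-cos(phi), -sin(phi), 0)
      start <- c(r_start * cos(phi), r_start * sin(phi), z)
      n_steps <- floor(r_start / step)
      n_rays <- n_rays + 1L
      h <- scan_one(start, dir, n_steps)
      if (!is.null(h)) { hits[[length(hits) + 1]] <- h; n_found <- n_found + 1L }
    }
  }
  # vertical rays from the bottom face moving up toward the tissue (the
  # detector side; the first crossing is the tissue dome, never the flat
  # holding-cup face at the top)
  for (ix in seq(1, d[1], by = max(1, floor(d[1] / 8)))) {
    for (iy in seq(1, d[2], by = max(1, floor(d[2] / 8)))) {
      start <- c(ax[[1]][ix], ax[[2]][iy], ax[[3]][1])
      n_rays <- n_rays + 1L
      h <- scan_one(start, c(0, 0, 1), d[3])
      if (!is.null(h)) { hits[[length(hits) + 1]] <- h; n_found <- n_found + 1L }
    }
  }
  if (n_found < (1 - max_failure_fraction) * n_rays || n_found == 0)
    stop(sprintf(
      "no surface: %d of %d rays found no amplitude increase",
      n_rays - n_found, n_rays), call. = FALSE)
  do.call(rbind, hits)
}

#' Fit an axis-aligned, axis-centered half ellipsoid to surface points
#'
#' Least-squares fit of `x^2/a^2 + y^2/b^2 + (z - z0)^2/cz^2 = 1` with the
#' center constrained to the scan axis. The quadric is fitted linearly in
#' `(x^2, y^2, z^2, z)` and converted back to semi-axes and center height.
#'
#' @param points Data frame or matrix with columns `x, y, z` (mm); at least
#'   9 non-degenerate points.
#' @return A `pact_ellipsoid` with an `rms_residual` attribute (RMS of the
#'   algebraic residual scaled by the mean semi-axis, mm-like units).
#' @export
fit_half_ellipsoid <- function(points) {
  p <- as.data.frame(points)
  if (!all(c("x", "y", "z") %in% names(p)))
    p <- stats::setNames(as.data.frame(matrix(as.matrix(points), ncol = 3)),
                         c("x", "y", "z"))
  if (nrow(p) < 9) stop("need at least 9 surface points", call. = FALSE)
  X <- cbind(p$x^2, p$y^2, p$z^2, p$z)
  qrX <- qr(X)
  if (qrX$rank < 4)
    stop("degenerate surface points: rank-deficient ellipsoid fit",
         call. = FALSE)
  theta <- qr.solve(qrX, rep(1, nrow(p)))
  if (theta[1] <= 0 || theta[2] <= 0 || theta[3] <= 0)
    stop("surface points do not fit a bounded ellipsoid", call. = FALSE)
  z0 <- -theta[4] / (2 * theta[3])
  scale <- 1 + theta[3] * z0^2
  if (scale <= 0)
    stop("surface points do not fit a bounded ellipsoid", call. = FALSE)
  semi <- sqrt(scale / theta[1:3])
  out <- ellipsoid_surface(semi, z0)
  # report the (approximately metric) radial residual
  dz <- p$z - z0
  rho <- sqrt((p$x / semi[1])^2 + (p$y / semi[2])^2 + (dz / semi[3])^2)
  geo <- (rho - 1) * sqrt(p$x^2 + p$y^2 + dz^2) / pmax(rho, 1e-12)
  attr(out, "rms_residual") <- sqrt(mean(geo^2))
  out
}

#' Two-pass dual-speed-of-sound reconstruction
#'
#' The full pipeline: (1) single-speed UBP initial image, (2) tissue surface
#' extraction, (3) half-ellipsoid fit, (4) dual-speed UBP with tissue and
#' coupling-fluid speeds assigned inside and outside the fitted surface.
#'
#' @param sinogram A `pact_sinogram`.
#' @param grid A `pact_volume` grid (0.13-mm voxels by default when built
#'   with [volume_grid()]).
#' @param c_water Coupling-fluid speed, mm/us.
#' @param c_tissue Tissue speed, mm/us.
#' @param surface Optional known `pact_ellipsoid`; when supplied the
#'   extraction and fitting passes are skipped.
#' @param ... Passed to [extract_surface()].
#' @return List with `volume` (dual-speed result), `initial` (single-speed
#'   volume), and `surface` (the fitted `pact_ellipsoid`).
#' @export
reconstruct_dual_sos <- function(sinogram, grid, c_water = 1.5,
                                 c_tissue = 1.54, surface = NULL, ...) {
  initial <- ubp_backproject(sinogram, grid, speed_model(c_water))
  if (is.null(surface)) {
    pts <- tryCatch(extract_surface(initial, ...), error = function(e)
      stop("dual-SOS surface extraction failed: ", conditionMessage(e),
           call. = FALSE))
    surface <- fit_half_ellipsoid(pts)
  }
  final <- ubp_backproject(sinogram, grid,
                           speed_model(c_water, c_tissue, surface))
  list(volume = final, initial = initial, surface = surface)
}
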
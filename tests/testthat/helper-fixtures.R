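# Shared fixtures and independent oracles for the test suite.

# A small detection setup: n_arcs x elements_per_arc elements, `firings`
# laser shots spanning the full 90-degree scan.
small_matrix <- function(elements_per_arc = 16, n_arcs = 2, firings = 5) {
  cfg <- system_config(elements_per_arc = elements_per_arc, n_arcs = n_arcs)
  geom <- build_nominal_array(cfg)
  duration <- (firings - 1) / cfg$laser_rep_rate
  speed <- if (firings > 1) (pi / 2) / duration else pi / 20
  traj <- scan_trajectory(speed, max(duration, 1e-3), cfg$laser_rep_rate)
  make_detection_matrix(geom, traj)
}

# Naive triple-loop universal back-projection reference: independent of the
# compiled production path (single speed, per-voxel normalized solid-angle
# weights, selectable delay interpolation).
ubp_reference <- function(sinogram, grid, c = 1.5,
                          interpolation = "linear", area_weights = TRUE) {
  tr <- sinogram$traces
  S <- dim(tr)[1]; N <- dim(tr)[2]; T <- dim(tr)[3]
  dt <- 1 / sinogram$sampling_rate
  t_grid <- sinogram$t0 + (seq_len(T) - 1) * dt
  d <- dim(grid$values)
  out <- array(0, d); wsum <- array(0, d)
  for (s in seq_len(S)) {
    for (n in seq_len(N)) {
      p <- tr[s, n, ]
      dp <- numeric(T)
      dp[2:(T - 1)] <- (p[3:T] - p[1:(T - 2)]) / (2 * dt)
      dp[1] <- (p[2] - p[1]) / dt
      dp[T] <- (p[T] - p[T - 1]) / dt
      b <- 2 * p - 2 * t_grid * dp
      e <- sinogram$matrix$positions[s, n, ]
      nv <- sinogram$matrix$normals[s, n, ]
      pw <- if (area_weights)
        max(sqrt(max(0, 1 - (e[3] / sqrt(sum(e^2)))^2)), 1e-6) else 1
      for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
        v <- grid$origin + (c(i, j, k) - 1) * grid$voxel_size
        dist <- sqrt(sum((v - e)^2))
        if (dist <= 0) next
        ts <- (dist / c - sinogram$t0) / dt
        if (ts < 0 || ts > T - 1) next
        bv <- if (interpolation == "linear") {
          i0 <- floor(ts); f <- ts - i0
          (1 - f) * b[i0 + 1] + f * b[min(i0 + 2, T)]
        } else b[round(ts) + 1]
        cth <- max(0, sum((v - e) * nv) / dist)
        w <- pw * cth / dist^2
        out[i, j, k] <- out[i, j, k] + w * bv
        wsum[i, j, k] <- wsum[i, j, k] + w
      }
    }
  }
  out[wsum > 0] <- out[wsum > 0] / wsum[wsum > 0]
  out
}

# Brute-force ray-marching oracle for the two-segment delay.
raymarch_delay <- function(v, e, surface, c_tissue, c_water, n = 1e5) {
  tt <- (seq_len(n) - 0.5) / n
  pts <- cbind(e[1] + tt * (v[1] - e[1]),
               e[2] + tt * (v[2] - e[2]),
               e[3] + tt * (v[3] - e[3]))
  len <- sqrt(sum((v - e)^2))
  inside <- ellipsoid_inside(surface, pts)
  L_t <- sum(inside) / n * len
  L_t / c_tissue + (len - L_t) / c_water
}

# Brute-force evaluation of the motion-gating rule: 3-point median filter
# (ends kept), first differences, strictly-greater threshold, both
# endpoints of each flagged jump removed. Independent of flag_motion.
brute_motion_keep <- function(x, threshold = 0.025) {
  n <- length(x)
  med <- x
  if (n >= 3)
    for (i in 2:(n - 1)) med[i] <- sort(x[(i - 1):(i + 1)])[2]
  keep <- rep(TRUE, n)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      if (abs(med[i + 1] - med[i]) > threshold) {
        keep[i] <- FALSE
        keep[i + 1] <- FALSE
      }
    }
  }
  keep
}

# Filled half-ellipsoid (dome) test volume with optional noise.
dome_volume <- function(semi = c(20, 20, 20), z0 = 6, vox = 0.5,
                        noise_sd = 0, seed = 1) {
  n <- c(90, 90, 50)
  grid <- volume_grid(n, vox, origin = c(-22.25, -22.25, -15))
  ax <- lapply(1:3, function(a) grid$origin[a] + (seq_len(n[a]) - 1) * vox)
  co <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  rho <- sqrt((co[, 1] / semi[1])^2 + (co[, 2] / semi[2])^2 +
              ((co[, 3] - z0) / semi[3])^2)
  grid$values <- array(as.numeric(rho <= 1 & co[, 3] <= z0), n)
  if (noise_sd > 0) {
    set.seed(seed)
    grid$values <- grid$values + array(stats::rnorm(prod(n), sd = noise_sd), n)
  }
  grid
}

# Point cloud on a half-ellipsoid surface (dome plus rim ring).
halfellipsoid_cloud <- function(n = 1000, semi = c(25, 25, 35), z0 = 5,
                                noise_sd = 0, rim_fraction = 0.2, seed = 1) {
  set.seed(seed)
  nr <- round(n * rim_fraction); nd <- n - nr
  u <- stats::runif(nd, -1, 0)
  phg <- stats::runif(nd, 0, 2 * pi)
  p <- data.frame(x = semi[1] * sqrt(1 - u^2) * cos(phg),
                  y = semi[2] * sqrt(1 - u^2) * sin(phg),
                  z = z0 + semi[3] * u)
  if (nr > 0) {
    pr <- stats::runif(nr, 0, 2 * pi)
    p <- rbind(p, data.frame(x = semi[1] * cos(pr), y = semi[2] * sin(pr),
                             z = z0))
  }
  if (noise_sd > 0) p <- p + stats::rnorm(3 * n, sd = noise_sd)
  p
}

# Exact time-of-flight measurement fixture for calibration tests.
tof_fixture <- function(elements_per_arc = 64, n_arcs = 4, M = 8,
                        alpha_range = c(0.98, 1.02), c_true = 1.5,
                        c_guess_rel = 1.01, source_err_mm = 2, seed = 1) {
  set.seed(seed)
  cfg <- system_config(elements_per_arc = elements_per_arc, n_arcs = n_arcs)
  geom <- build_nominal_array(cfg)
  N <- nrow(geom$positions)
  alpha_true <- stats::runif(N, alpha_range[1], alpha_range[2])
  gp <- apply_radial_factors(geom, alpha_true)
  src <- cbind(stats::runif(M, -15, 15), stats::runif(M, -15, 15),
               stats::runif(M, -5, 25))
  tof <- matrix(0, M, N)
  for (m in seq_len(M))
    tof[m, ] <- sqrt(colSums((t(gp$positions) - src[m, ])^2)) / c_true
  meas <- tof_measurement(
    tof, c_true * c_guess_rel,
    src + matrix(stats::rnorm(M * 3, sd = source_err_mm / sqrt(3)), M, 3),
    geom$positions)
  list(meas = meas, alpha_true = alpha_true, src_true = src,
       c_true = c_true, geom = geom)
}
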
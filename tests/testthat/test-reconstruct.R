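test_that("the antialiasing cutoff law is monotone and full-band on axis", {
  d <- seq(0, 60, by = 1)
  fc <- antialias_cutoff(d)
  expect_true(all(diff(fc) <= 1e-12))
  expect_equal(fc[1], 2.25 * 1.98)
  # filtering a grid confined to the axis is a pass-through for the
  # retained original channels
  mat <- small_matrix(elements_per_arc = 8, n_arcs = 2, firings = 3)
  ph <- phantom(spheres = data.frame(x = 0, y = 0, z = 2, radius = 1,
                                     mu_a = 1))
  sg <- simulate_scan(ph, mat, noise_sd = 0)
  out <- antialias_filter(sg, grid_extent = 0.1)
  orig <- out$meta$original_channels
  expect_length(orig, dim(sg$traces)[2])
  expect_lt(max(abs(out$traces[, orig, ] - sg$traces)),
            1e-6 * max(abs(sg$traces)))
  expect_equal(out$meta$f_cut_MHz, 2.25 * (1 + 0.98))
})

test_that("the distance-dependent low-pass keeps the carrier and kills it far out", {
  mat <- small_matrix(elements_per_arc = 4, n_arcs = 2, firings = 2)
  S <- dim(mat$positions)[1]; N <- dim(mat$positions)[2]
  tt <- (0:511) / 40
  burst <- sin(2 * pi * 2.25 * tt) * exp(-(tt - 6.4)^2 / 2)
  traces <- array(rep(burst, each = S * N), c(S, N, 512))
  sg <- structure(list(traces = traces, sampling_rate = 40, t0 = 0,
                       c = 1.5, matrix = mat, meta = list()),
                  class = "pact_sinogram")
  near <- antialias_filter(sg, grid_extent = 5, upsample = FALSE)
  expect_gt(max(abs(near$traces[1, 1, ])), 0.9 * max(abs(burst)))
  # choose a distance where the cutoff falls below 1 MHz
  d_far <- 2.25 * 1.98 * 10 / 0.9
  far <- antialias_filter(sg, grid_extent = d_far, upsample = FALSE)
  expect_lt(max(abs(far$traces[1, 1, ])), 10^(-20 / 20) * max(abs(burst)))
  expect_lt(far$meta$f_cut_MHz, 1)
})

test_that("UBP localizes a small sphere to within one voxel and is linear", {
  mat <- small_matrix(elements_per_arc = 32, n_arcs = 4, firings = 5)
  ph <- phantom(spheres = data.frame(x = 5, y = 0, z = -5, radius = 0.3,
                                     mu_a = 1))
  sg <- simulate_scan(ph, mat, noise_sd = 0)
  grid <- volume_grid(c(33, 33, 33), 0.13, origin = c(5 - 16 * 0.13,
                                                      -16 * 0.13,
                                                      -5 - 16 * 0.13))
  vol <- ubp_backproject(sg, grid)
  im <- which(vol$values == max(vol$values), arr.ind = TRUE)[1, ]
  peak <- grid$origin + (im - 1) * 0.13
  expect_lt(max(abs(peak - c(5, 0, -5))), 0.13 + 1e-9)
  # linearity of the reconstruction in the sinogram
  sg2 <- sg; sg2$traces <- 2 * sg$traces
  vol2 <- ubp_backproject(sg2, grid)
  expect_lt(max(abs(vol2$values - 2 * vol$values)),
            1e-9 * max(abs(vol$values)))
  ph_b <- phantom(spheres = data.frame(x = 4.5, y = 0.5, z = -5,
                                       radius = 0.3, mu_a = 0.6))
  sg_b <- simulate_scan(ph_b, mat, noise_sd = 0, t0 = sg$t0,
                        n_samples = dim(sg$traces)[3])
  sg_ab <- sg
  sg_ab$traces <- sg$traces + sg_b$traces
  v_ab <- ubp_backproject(sg_ab, grid)
  v_b <- ubp_backproject(sg_b, grid)
  expect_lt(max(abs(v_ab$values - vol$values - v_b$values)),
            1e-9 * max(abs(v_ab$values)))
})

test_that("the production back-projector matches the naive reference", {
  mat <- small_matrix(elements_per_arc = 16, n_arcs = 2, firings = 5)
  ph <- phantom(spheres = data.frame(x = c(2, -3), y = c(1, 0),
                                     z = c(3, 6), radius = c(0.5, 0.8),
                                     mu_a = c(1, 0.5)))
  sg <- simulate_scan(ph, mat, noise_sd = 0)
  grid <- volume_grid(c(16, 16, 16), 0.5, origin = c(-3.75, -3.75, 0.25))
  for (interp in c("linear", "nearest")) {
    vol <- ubp_backproject(sg, grid, speed_model(1.5),
                           interpolation = interp)
    ref <- ubp_reference(sg, grid, c = 1.5, interpolation = interp)
    expect_lt(max(abs(vol$values - ref)), 1e-9 * max(abs(ref)))
  }
})

test_that("surface extraction recovers a digital dome", {
  vol <- dome_volume()
  pts <- extract_surface(vol)
  d <- sqrt(pts$x^2 + pts$y^2 + (pts$z - 6)^2) - 20
  expect_lt(sqrt(mean(d^2)), 0.5)
  # noisy dome: at least 90% of rays land within 1 mm of the true surface
  voln <- dome_volume(noise_sd = 0.1, seed = 2)
  ptsn <- extract_surface(voln)
  dn <- abs(sqrt(ptsn$x^2 + ptsn$y^2 + (ptsn$z - 6)^2) - 20)
  expect_gte(mean(dn < 1), 0.9)
  # a uniform zero volume has no surface
  expect_error(extract_surface(volume_grid(c(20, 20, 20), 1)), "no surface")
})

test_that("half-ellipsoid fitting is exact without noise and robust with it", {
  pts <- halfellipsoid_cloud(400, semi = c(25, 25, 35), z0 = 5, seed = 3)
  fit <- fit_half_ellipsoid(pts)
  expect_lt(max(abs(fit$semi_axes - c(25, 25, 35))), 1e-6)
  expect_lt(abs(fit$center_z - 5), 1e-6)
  expect_lt(attr(fit, "rms_residual"), 1e-6)
  # spherical points recover a sphere
  sp <- halfellipsoid_cloud(300, semi = c(20, 20, 20), z0 = 0, seed = 4)
  fs <- fit_half_ellipsoid(sp)
  expect_lt(max(abs(fs$semi_axes - 20)), 1e-6)
  # 1-mm point noise, 1000-point clouds: median semi-axis error over seeds
  # stays below 0.5 mm
  errs <- sapply(1:5, function(s) {
    f <- fit_half_ellipsoid(halfellipsoid_cloud(1000, noise_sd = 1,
                                                seed = s))
    max(abs(f$semi_axes - c(25, 25, 35)))
  })
  expect_lt(median(errs), 0.5)
  expect_error(fit_half_ellipsoid(pts[1:5, ]), "9")
  flat <- data.frame(x = rnorm(20), y = rnorm(20), z = 0)
  expect_error(fit_half_ellipsoid(flat))
})

test_that("two-segment delays collapse correctly and match ray marching", {
  surf <- ellipsoid_surface(c(25, 25, 35), 5)
  # equal speeds: plain distance delay for arbitrary pairs
  sp_eq <- speed_model(1.5, 1.5, surf)
  v <- c(3, 4, -5); e <- c(0, -90, -90)
  expect_equal(dual_sos_delay(v, e, sp_eq),
               sqrt(sum((v - e)^2)) / 1.5, tolerance = 1e-12)
  # a ray missing the ellipsoid entirely: pure water delay
  sp <- speed_model(1.5, 1.54, surf)
  v2 <- c(100, 100, -50); e2 <- c(120, 100, -50)
  expect_equal(dual_sos_delay(v2, e2, sp), 20 / 1.5, tolerance = 1e-12)
  # 100 random voxel/element pairs against a 1e5-step ray-marching oracle
  set.seed(6)
  worst <- 0
  for (i in 1:100) {
    v3 <- c(runif(1, -20, 20), runif(1, -20, 20), runif(1, -25, 4))
    az <- runif(1, 0, 2 * pi); el <- runif(1, -pi / 2, 0)
    e3 <- 130 * c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
    got <- dual_sos_delay(v3, e3, sp)
    want <- raymarch_delay(v3, e3, surf, 1.54, 1.5)
    worst <- max(worst, abs(got - want) * 1.5)  # us -> mm at water speed
  }
  expect_lt(worst, 1e-4)
  expect_error(dual_sos_delay(v, v, sp), "zero-length")
})

test_that("dual-speed reconstruction collapses to single speed when equal", {
  mat <- small_matrix(elements_per_arc = 16, n_arcs = 4, firings = 3)
  ph <- phantom(spheres = data.frame(x = 0, y = 0, z = 8, radius = 0.4,
                                     mu_a = 1))
  sg <- simulate_scan(ph, mat, noise_sd = 0)
  grid <- volume_grid(c(21, 21, 21), 0.3, origin = c(-3, -3, 5))
  surf <- ellipsoid_surface(c(20, 20, 25), 15)
  res <- reconstruct_dual_sos(sg, grid, c_water = 1.5, c_tissue = 1.5,
                              surface = surf)
  expect_lt(max(abs(res$volume$values - res$initial$values)),
            1e-6 * max(abs(res$initial$values)))
  expect_identical(res$surface, surf)
})

test_that("dual-speed delays improve localization in mismatched media", {
  # a sphere inside a faster-tissue dome, simulated with per-pair dual
  # delays, reconstructs closer to truth with the dual model than with a
  # single water speed
  cfg <- system_config(elements_per_arc = 32, n_arcs = 4)
  geom <- build_nominal_array(cfg)
  traj <- scan_trajectory((pi / 2) / 0.4, 0.4, 10)
  mat <- make_detection_matrix(geom, traj)
  surf <- ellipsoid_surface(c(22, 22, 28), 18)
  sp <- speed_model(1.5, 1.54, surf)
  ctr <- c(0, 0, 8)
  # simulate by stretching each trace's arrival to the dual-model delay:
  # emit the N-wave at the dual delay instead of d / c_water
  fl <- pact3d:::flatten_detmat(mat)
  tau <- dual_sos_delay(matrix(ctr, nrow(fl$positions), 3, byrow = TRUE),
                        fl$positions, sp)
  t0 <- 70; T <- 1400; fs <- 40
  t_grid <- t0 + (seq_len(T) - 1) / fs
  a <- 0.4
  S <- dim(mat$positions)[1]; N <- dim(mat$positions)[2]
  traces <- array(0, c(S, N, T))
  d_all <- sqrt(rowSums((fl$positions - matrix(ctr, nrow(fl$positions), 3,
                                               byrow = TRUE))^2))
  for (j in seq_len(nrow(fl$positions))) {
    s <- (j - 1) %/% N + 1; n <- (j - 1) %% N + 1
    u <- (tau[j] - t_grid) * 1.5   # mm offset from the wavefront
    on <- abs(u) < a
    traces[s, n, on] <- u[on] / (2 * d_all[j])
  }
  sg <- structure(list(traces = traces, sampling_rate = fs, t0 = t0,
                       c = 1.5, matrix = mat, meta = list()),
                  class = "pact_sinogram")
  grid <- volume_grid(c(25, 25, 25), 0.13,
                      origin = c(-12, -12, 8 / 0.13 - 12) * 0.13)
  v_single <- ubp_backproject(sg, grid, speed_model(1.5))
  v_dual <- ubp_backproject(sg, grid, sp)
  locate <- function(v) {
    im <- which(v$values == max(v$values), arr.ind = TRUE)[1, ]
    sqrt(sum((grid$origin + (im - 1) * 0.13 - ctr)^2))
  }
  expect_lt(locate(v_dual), locate(v_single))
})

test_that("volume grids default to 0.13-mm isotropic voxels", {
  g <- volume_grid(c(10, 10, 10))
  expect_equal(g$voxel_size, 0.13)
  expect_error(volume_grid(c(10, 10, 10), voxel_size = 0), "voxel_size")
})
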
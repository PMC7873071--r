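test_that("the sphere N-wave has the closed form's support and symmetry", {
  r <- sqrt(sum((c(20, 0, 0) - c(0, 0, 0))^2))
  cc <- 1.5
  # zero crossing exactly at the center arrival time
  expect_equal(sphere_signal(c(0, 0, 0), 0.5, 1, c(20, 0, 0), r / cc, cc), 0)
  # support duration 2 a / c: radius 0.5 mm at 1.5 mm/us -> 2/3 us
  t <- seq(r / cc - 1, r / cc + 1, by = 1e-4)
  p <- sphere_signal(c(0, 0, 0), 0.5, 1, c(20, 0, 0), t, cc)
  on <- which(p != 0)
  expect_equal((max(on) - min(on)) * 1e-4, 2 * 0.5 / cc, tolerance = 2e-4)
  # bipolar symmetry: quadrature on a grid symmetric about r/c integrates to 0
  ts <- r / cc + seq(-0.4, 0.4, by = 1e-4)
  ps <- sphere_signal(c(0, 0, 0), 0.5, 1, c(20, 0, 0), ts, cc)
  expect_lt(abs(sum(ps) * 1e-4), 1e-6 * max(abs(ps)) * (2 * 0.5 / cc))
  expect_error(sphere_signal(c(0, 0, 0), 5, 1, c(1, 0, 0), t, cc), "inside")
})

test_that("the transducer band-pass rejects DC and keeps the carrier", {
  resp <- transducer_response()
  out <- apply_transducer_response(rep(1, 512), resp, 40)
  expect_lt(max(abs(out)), 1e-9)
  tt <- (0:511) / 40
  carrier <- sin(2 * pi * 2.25 * tt)
  y <- apply_transducer_response(carrier, resp, 40)
  expect_equal(max(abs(y[100:400])), 1, tolerance = 0.01)
  # a tone at 5x the center frequency drops by far more than 20 dB under
  # the Gaussian spectrum
  y5 <- apply_transducer_response(sin(2 * pi * 11.25 * tt), resp, 40)
  expect_lt(20 * log10(max(abs(y5[100:400]))), -20)
  expect_error(transducer_response(fractional_bandwidth = 2.5), "bandwidth")
})

test_that("simulated scans honor linearity, timing and determinism", {
  mat <- small_matrix(elements_per_arc = 8, n_arcs = 2, firings = 3)
  # empty phantom -> all-zero sinogram
  empty <- simulate_scan(phantom(), mat, noise_sd = 0)
  expect_true(all(empty$traces == 0))
  # first arrival of a tiny central sphere at every element: 130 / c
  ph0 <- phantom(spheres = data.frame(x = 0, y = 0, z = 0, radius = 0.05,
                                      mu_a = 1))
  sg0 <- simulate_scan(ph0, mat, response = NULL, noise_sd = 0)
  T <- dim(sg0$traces)[3]
  t_grid <- sg0$t0 + (seq_len(T) - 1) / sg0$sampling_rate
  onsets <- apply(abs(sg0$traces) > 0, c(1, 2), function(z) t_grid[which(z)[1]])
  expect_lt(max(abs(onsets - 130 / 1.5)), 1 / 40 + 1e-9)
  # linearity: sum of phantoms equals sum of sinograms; doubling mu_a doubles
  phA <- phantom(spheres = data.frame(x = 3, y = 0, z = 5, radius = 1,
                                      mu_a = 0.4))
  phB <- phantom(spheres = data.frame(x = -4, y = 2, z = 8, radius = 1.5,
                                      mu_a = 0.7))
  phAB <- phantom(spheres = rbind(phA$spheres, phB$spheres))
  args <- list(matrix = mat, noise_sd = 0, t0 = 70, n_samples = 800)
  sgA <- do.call(simulate_scan, c(list(phA), args))
  sgB <- do.call(simulate_scan, c(list(phB), args))
  sgAB <- do.call(simulate_scan, c(list(phAB), args))
  expect_lt(max(abs(sgAB$traces - sgA$traces - sgB$traces)),
            1e-9 * max(abs(sgAB$traces)))
  ph2 <- phantom(spheres = transform(phA$spheres, mu_a = 0.8))
  sg2 <- do.call(simulate_scan, c(list(ph2), args))
  expect_equal(sg2$traces, 2 * sgA$traces, tolerance = 1e-12)
  # seeded determinism is bit-exact
  n1 <- simulate_scan(phA, mat, noise_sd = 0.1, seed = 42)
  n2 <- simulate_scan(phA, mat, noise_sd = 0.1, seed = 42)
  expect_identical(n1$traces, n2$traces)
  expect_error(simulate_scan(phA, mat, c = -1), "'c'")
})

test_that("point-source sessions retain exact ground-truth times of flight", {
  geom <- build_nominal_array(system_config(elements_per_arc = 8, n_arcs = 2))
  src <- rbind(c(0, 0, 0), c(5, -3, 10))
  ses <- make_point_source_session(src, geom, response = NULL, c = 1.5)
  # source at the origin: identical time of flight at every element
  expect_lt(diff(range(ses$tof[1, ])), 1e-12)
  # ground truth is |source - element| / c for every pair
  for (m in 1:2) {
    d <- sqrt(colSums((t(geom$positions) - src[m, ])^2))
    expect_equal(ses$tof_true[m, ], d / 1.5, tolerance = 1e-12)
  }
  # radial perturbations propagate exactly into the times of flight
  alpha <- runif(nrow(geom$positions), 0.99, 1.01)
  gp <- apply_radial_factors(geom, alpha)
  ses2 <- make_point_source_session(src, gp, response = NULL, c = 1.5)
  d2 <- sqrt(colSums((t(gp$positions) - src[2, ])^2))
  expect_equal(ses2$tof_true[2, ], d2 / 1.5, tolerance = 1e-12)
  expect_warning(make_point_source_session(c(200, 0, 0), geom,
                                           response = NULL), "outside")
})

test_that("phantom presets encode the breast-study absorption contrast", {
  ph <- make_breast_phantom()
  expect_equal(unique(ph$spheres$mu_a) / ph$background_mu_a, 2.1)
  expect_equal(ph$fluence_decay, 0.9)
  expect_true(1 %in% (2 * ph$spheres$radius))  # includes a 1-mm tumor
  expect_true(all(ph$spheres$z == 40 - 20))    # 2 cm below the dome top
  vp <- make_vessel_phantom()
  expect_true(any(abs(2 * vp$cylinders$radius - 0.4) < 1e-12))
  expect_error(make_breast_phantom("nope"), "breast")
  expect_error(make_vessel_phantom("nope"), "branching")
})

test_that("functional series designs match their stated timing", {
  lab <- make_label_volume(20)
  expect_equal(max(unclass(lab)), 20)
  ser <- simulate_functional_series(lab, "resting", seed = 3)
  expect_equal(dim(ser$data)[4], 240)   # 8 min at 0.5 Hz
  expect_equal(ser$frame_rate, 0.5)
  # a fully shared latent with zero noise makes paired region means identical
  ser2 <- simulate_functional_series(lab, "resting", seed = 4,
                                     shared_fraction = 1, noise_sd = 0)
  pr <- ser2$ground_truth$pairs[1, ]
  m1 <- apply(ser2$data, 4, function(f) mean(f[unclass(lab) == pr[1]]))
  m2 <- apply(ser2$data, 4, function(f) mean(f[unclass(lab) == pr[2]]))
  expect_equal(m1, m2, tolerance = 1e-12)
  # stimulation period is 24 s (12 s on + 12 s off)
  st <- simulate_functional_series(lab, "stimulation", seed = 5,
                                   noise_sd = 0)
  expect_equal(st$ground_truth$period_s, 24)
  box <- st$ground_truth$boxcar
  expect_equal(box[1:12], rep(c(1, 0), each = 6))
  expect_identical(
    simulate_functional_series(lab, "resting", seed = 9)$data,
    simulate_functional_series(lab, "resting", seed = 9)$data)
  one_region <- structure(array(1L, c(4, 4, 2)),
                          class = c("pact_roiset", "array"))
  expect_error(simulate_functional_series(one_region, "resting"),
               "at least 2")
})
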
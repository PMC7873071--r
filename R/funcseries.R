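#' Build a block label volume with contralateral region pairs
#'
#' Lays out `n_regions` rectangular regions in a small volume, half in the
#' left hemisphere (x below the midline) and their mirror images in the
#' right, so region `k` pairs with region `k + n_regions/2`. Used as input
#' to [simulate_functional_series()] and the ROI analyses.
#'
#' @param n_regions Even number of regions (default 20).
#' @param dim Volume dimensions (x, y, z) in voxels.
#' @return A `pact_roiset`: integer label array (0 = background) with
#'   attributes `pairs` (P x 2 matrix of contralateral pairs) and `names`.
#' @export
make_label_volume <- function(n_regions = 20, dim = c(12, 10, 6)) {
  if (n_regions %% 2 != 0 || n_regions < 2)
    stop("'n_regions' must be an even number >= 2", call. = FALSE)
  P <- n_regions / 2
  labels <- array(0L, dim)
  # tile the left hemisphere (x in 1..dim[1]/2 - gap) with P blocks
  nx <- floor(dim[1] / 2) - 1
  grid <- expand.grid(y = seq_len(dim[2]), z = seq_len(dim[3]))
  ny_b <- max(1, floor(dim[2] / ceiling(P / dim[3])))
  blk <- 0L
  for (z in seq_len(dim[3])) {
    for (yb in seq_len(ceiling(dim[2] / ny_b))) {
      if (blk >= P) break
      blk <- blk + 1L
      ys <- ((yb - 1) * ny_b + 1):min(yb * ny_b, dim[2])
      labels[seq_len(nx), ys, z] <- blk
      labels[(dim[1] - nx + 1):dim[1], ys, z] <- blk + P
    }
  }
  if (max(labels) < n_regions)
    stop("volume too small to host ", n_regions, " regions", call. = FALSE)
  structure(labels,
            pairs = cbind(seq_len(P), seq_len(P) + P),
            names = paste0("R", seq_len(n_regions)),
            class = c("pact_roiset", "array"))
}

# Band-limited (0.01-0.08 Hz) unit-variance latent signal.
latent_lowfreq <- function(n_frames, frame_rate, low = 0.01, high = 0.08) {
  bf <- signal::butter(2, c(low, high) / (frame_rate / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n_frames + 200))
  x <- x[101:(100 + n_frames)]
  x / stats::sd(x)
}

#' Simulate a 4D functional volumetric series with known ground truth
#'
#' Generates resting-state, stimulation, or hypoxia designs on a region
#' label volume at the system's 0.5-Hz volumetric rate.
#'
#' \describe{
#' \item{resting}{240 frames (8 min at 0.5 Hz). Each contralateral region
#'   pair shares a low-frequency (0.01-0.08 Hz) latent signal with weight
#'   `shared_fraction`, mixed with an independent band-limited signal of
#'   weight `1 - shared_fraction`, plus white voxel noise.}
#' \item{stimulation}{Boxcar-driven responses with a 24-s period (12 s on,
#'   12 s off) in `stim_regions`.}
#' \item{hypoxia}{Global multiplicative decline to `1 - dip_depth` and
#'   recovery (trapezoidal profile).}
#' }
#'
#' @param label_volume A `pact_roiset` from [make_label_volume()].
#' @param design One of `"resting"`, `"stimulation"`, `"hypoxia"`.
#' @param seed RNG seed.
#' @param n_frames Number of volumes (default 240).
#' @param frame_rate Volumetric rate, Hz (default 0.5).
#' @param shared_fraction Weight of the shared latent within a pair.
#' @param fluct_amplitude Amplitude of resting fluctuations relative to the
#'   baseline of 1.
#' @param noise_sd White voxel noise SD.
#' @param stim_regions Region labels driven by the stimulus.
#' @param stim_amplitude On-block response amplitude (relative).
#' @param stim_period_s Stimulation cycle period in seconds.
#' @param dip_depth Hypoxia dip depth (0.2 = 20 percent signal drop).
#' @return A `pact_series`: list with `data` (4D array x,y,z,t),
#'   `frame_rate`, `mask`, `labels`, `design`, `processed` (character vector
#'   of applied processing stages) and `ground_truth`.
#' @export
simulate_functional_series <- function(label_volume,
                                       design = c("resting", "stimulation",
                                                  "hypoxia"),
                                       seed = 1L, n_frames = 240,
                                       frame_rate = 0.5,
                                       shared_fraction = 0.7,
                                       fluct_amplitude = 0.05,
                                       noise_sd = 0.01,
                                       stim_regions = c(1L, 2L),
                                       stim_amplitude = 0.1,
                                       stim_period_s = 24,
                                       dip_depth = 0.2) {
  design <- match.arg(design)
  labels <- unclass(label_volume)
  R <- max(labels)
  if (design == "resting" && R < 2)
    stop("resting design needs at least 2 regions", call. = FALSE)
  set.seed(as.integer(seed))
  dims <- dim(labels)
  region_ts <- matrix(0, n_frames, R)
  gt <- list(design = design)
  if (design == "resting") {
    pairs <- attr(label_volume, "pairs")
    if (is.null(pairs)) {
      P <- floor(R / 2)
      pairs <- cbind(seq_len(P), seq_len(P) + P)
    }
    for (p in seq_len(nrow(pairs))) {
      shared <- latent_lowfreq(n_frames, frame_rate)
      for (r in pairs[p, ]) {
        indep <- latent_lowfreq(n_frames, frame_rate)
        region_ts[, r] <- fluct_amplitude *
          (shared_fraction * shared + (1 - shared_fraction) * indep)
      }
    }
    unpaired <- setdiff(seq_len(R), as.vector(pairs))
    for (r in unpaired)
      region_ts[, r] <- fluct_amplitude * latent_lowfreq(n_frames, frame_rate)
    gt$pairs <- pairs
    gt$shared_fraction <- shared_fraction
  } else if (design == "stimulation") {
    frames_per_cycle <- stim_period_s * frame_rate
    if (abs(frames_per_cycle - round(frames_per_cycle)) > 1e-9)
      stop("stimulation period must be frame-aligned", call. = FALSE)
    phase <- (seq_len(n_frames) - 1) %% round(frames_per_cycle)
    boxcar <- as.numeric(phase < round(frames_per_cycle) / 2)
    for (r in stim_regions) region_ts[, r] <- stim_amplitude * boxcar
    gt$stim_regions <- stim_regions
    gt$stim_amplitude <- stim_amplitude
    gt$boxcar <- boxcar
    gt$period_s <- stim_period_s
  } else {  # hypoxia
    b1 <- floor(n_frames * 0.2); b2 <- floor(n_frames * 0.4)
    b3 <- floor(n_frames * 0.6); b4 <- floor(n_frames * 0.8)
    prof <- rep(1, n_frames)
    prof[(b1 + 1):b2] <- 1 - dip_depth * seq_len(b2 - b1) / (b2 - b1)
    prof[(b2 + 1):b3] <- 1 - dip_depth
    prof[(b3 + 1):b4] <- 1 - dip_depth +
      dip_depth * seq_len(b4 - b3) / (b4 - b3)
    gt$dip_depth <- dip_depth
    gt$profile <- prof
    gt$baseline_window <- seq_len(b1)
  }
  data <- array(0, c(dims, n_frames))
  vox_noise <- if (noise_sd > 0)
    array(stats::rnorm(prod(dims) * n_frames, sd = noise_sd),
          c(dims, n_frames)) else 0
  base <- array(1, dims)
  for (t in seq_len(n_frames)) {
    frame <- base
    if (design == "hypoxia") {
      frame <- frame * gt$profile[t]
    } else {
      for (r in seq_len(R)) {
        idx <- labels == r
        frame[idx] <- frame[idx] * (1 + region_ts[t, r])
      }
    }
    data[, , , t] <- frame
  }
  data <- data + vox_noise
  gt$region_ts <- region_ts
  structure(list(data = data, frame_rate = frame_rate,
                 mask = labels > 0, labels = labels, design = design,
                 processed = character(), ground_truth = gt,
                 seed = as.integer(seed)),
            class = "pact_series")
}
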
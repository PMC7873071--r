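#' Write a sinogram to the HDF5 schema
#'
#' Layout (schema version 1):
#' \preformatted{
#'   /signals            S x N x T pressure traces
#'   /meta               sampling_rate_MHz, t0_us, laser_rep_rate_Hz,
#'                       angular_speed_rad_s, seed, schema_version, c_mm_us
#'   /geometry           element positions (N x 3), normals, arc_index,
#'                       rotation_angles (S), firing_times (S), config (JSON)
#'   /calibration        optional: alpha (N), c
#' }
#' Element ordering is arc-major then along-arc (deepest element first), as
#' produced by [build_nominal_array()].
#'
#' @param sinogram A `pact_sinogram`.
#' @param path Output `.h5` path (overwritten).
#' @param calibration Optional list with `alpha` and `c` to store.
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(sinogram, path, calibration = NULL) {
  stopifnot(inherits(sinogram, "pact_sinogram"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(sinogram$traces, path, "signals")
  rhdf5::h5createGroup(path, "meta")
  meta <- list(
    schema_version = 1L,
    sampling_rate_MHz = sinogram$sampling_rate,
    t0_us = sinogram$t0,
    c_mm_us = sinogram$c %||% NA_real_,
    seed = sinogram$meta$seed %||% NA_integer_,
    noise_sd = sinogram$meta$noise_sd %||% NA_real_)
  g <- sinogram$matrix$geometry
  cfg <- g$config
  if (!is.null(cfg)) {
    meta$laser_rep_rate_Hz <- cfg$laser_rep_rate
  }
  ft <- sinogram$matrix$firing_times
  ra <- sinogram$matrix$rotation_angles
  if (length(ft) > 1)
    meta$angular_speed_rad_s <- (ra[2] - ra[1]) / (ft[2] - ft[1])
  for (nm in names(meta)) rhdf5::h5write(meta[[nm]], path,
                                         paste0("meta/", nm))
  rhdf5::h5createGroup(path, "geometry")
  rhdf5::h5write(g$positions, path, "geometry/positions")
  rhdf5::h5write(g$normals, path, "geometry/normals")
  rhdf5::h5write(as.integer(g$arc_index), path, "geometry/arc_index")
  rhdf5::h5write(ra, path, "geometry/rotation_angles")
  rhdf5::h5write(ft, path, "geometry/firing_times")
  if (!is.null(cfg))
    rhdf5::h5write(as.character(jsonlite::toJSON(unclass(cfg),
                                                 auto_unbox = TRUE)),
                   path, "geometry/config_json")
  if (!is.null(g$alpha))
    rhdf5::h5write(g$alpha, path, "geometry/alpha")
  if (!is.null(calibration)) {
    rhdf5::h5createGroup(path, "calibration")
    if (!is.null(calibration$alpha))
      rhdf5::h5write(calibration$alpha, path, "calibration/alpha")
    if (!is.null(calibration$c))
      rhdf5::h5write(calibration$c, path, "calibration/c")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a sinogram written by [write_sinogram()]
#'
#' @param path `.h5` path.
#' @return A `pact_sinogram` (with `calibration` attached when present).
#' @export
read_sinogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ls <- rhdf5::h5ls(path)
  paths <- paste0(sub("^/$", "", ls$group), "/", ls$name)
  need <- c("/signals", "/meta", "/geometry")
  missing <- setdiff(need, c(paths, paste0("/", ls$name[ls$group == "/"])))
  if (length(missing))
    stop("sinogram schema error: missing ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  ver <- as.integer(rhdf5::h5read(path, "meta/schema_version"))
  if (!identical(ver, 1L))
    stop("unsupported sinogram schema_version ", ver,
         " (supported: 1)", call. = FALSE)
  traces <- rhdf5::h5read(path, "signals")
  rd <- function(p) tryCatch(rhdf5::h5read(path, p), error = function(e) NULL)
  cfg_json <- rd("geometry/config_json")
  cfg <- if (!is.null(cfg_json)) {
    co <- jsonlite::fromJSON(as.character(cfg_json))
    do.call(system_config, co[names(co) %in% names(formals(system_config))])
  } else NULL
  geom <- structure(list(
    positions = rd("geometry/positions"),
    normals = rd("geometry/normals"),
    arc_index = as.integer(rd("geometry/arc_index")),
    element_ids = seq_len(nrow(rd("geometry/positions"))),
    config = cfg, alpha = rd("geometry/alpha")),
    class = "pact_geometry")
  traj <- structure(list(
    firing_times = as.numeric(rd("geometry/firing_times")),
    rotation_angles = as.numeric(rd("geometry/rotation_angles"))),
    class = "pact_trajectory")
  mat <- make_detection_matrix(geom, traj)
  cal <- NULL
  if ("/calibration" %in% paths || any(ls$group == "/calibration"))
    cal <- list(alpha = as.numeric(rd("calibration/alpha")),
                c = as.numeric(rd("calibration/c")))
  out <- structure(list(
    traces = traces,
    sampling_rate = as.numeric(rhdf5::h5read(path, "meta/sampling_rate_MHz")),
    t0 = as.numeric(rhdf5::h5read(path, "meta/t0_us")),
    c = as.numeric(rd("meta/c_mm_us")),
    matrix = mat,
    meta = list(seed = as.integer(rd("meta/seed")),
                noise_sd = as.numeric(rd("meta/noise_sd")))),
    class = "pact_sinogram")
  out$calibration <- cal
  rhdf5::h5closeAll()
  out
}

#' Write a reconstructed volume as NIfTI
#'
#' Voxel spacing is recorded in the header; the coordinate convention
#' (origin at the hemisphere center, +Z up, scan about +Z) is recorded in
#' the description field.
#'
#' @param volume A `pact_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pact_volume"))
  img <- RNifti::asNifti(volume$values)
  img <- RNifti::`pixdim<-`(img, rep(volume$voxel_size, 3))
  aff <- diag(c(rep(volume$voxel_size, 3), 1))
  aff[1:3, 4] <- volume$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  attr(img, "description") <- "pact3d frame: origin=hemisphere center,+Z up"
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume into a `pact_volume`
#'
#' @param path NIfTI path.
#' @return A `pact_volume` (voxel size and origin from the header).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  aff <- RNifti::xform(img)
  vox <- sqrt(sum(aff[1:3, 1]^2))
  if (vox <= 0) vox <- hdr$pixdim[2]
  org <- aff[1:3, 4]
  volume_grid(dim(img), vox, as.numeric(org), values = array(as.numeric(img),
                                                             dim(img)))
}

#' Write / read a 4D functional series as NIfTI
#'
#' @param series A `pact_series`.
#' @param path NIfTI path.
#' @return `path` ([write_series()]); a `pact_series` without labels
#'   ([read_series()]; supply ROI labels separately).
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "pact_series"))
  img <- RNifti::asNifti(series$data)
  img <- RNifti::`pixdim<-`(img, c(1, 1, 1, 1 / series$frame_rate))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  tr <- hdr$pixdim[5]
  structure(list(data = array(as.numeric(img), dim(img)),
                 frame_rate = if (tr > 0) 1 / tr else 0.5,
                 mask = NULL, labels = NULL, design = "unknown",
                 processed = character(), ground_truth = NULL),
            class = "pact_series")
}

#' Read a run configuration (YAML or JSON)
#'
#' Unknown top-level keys are rejected to catch typos in configs.
#'
#' @param path `.yaml`/`.yml`/`.json` path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c(names(formals(system_config)), "preset", "seed", "voxel_size",
             "c_water", "c_tissue", "noise_sd", "duration",
             "angular_speed", "threshold_us", "kernel", "depth_preset",
             "denoise_method", "scales", "w_filtered", "low", "high",
             "n_regions", "design")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg
}

#' Write a provenance sidecar for an output artifact
#'
#' Records the generating configuration, seed, package version and input
#' file hashes next to the artifact so it can be regenerated.
#'
#' @param out_path Artifact path (sidecar becomes `<out_path>.prov.json`).
#' @param config List of parameters used.
#' @param inputs Character vector of input file paths (hashed).
#' @param seed Seed used, if any.
#' @return Sidecar path, invisibly.
#' @export
write_provenance <- function(out_path, config = list(), inputs = character(),
                             seed = NULL) {
  hash_file <- function(p) {
    con <- file(p, "rb"); on.exit(close(con))
    sz <- file.info(p)$size
    raw <- readBin(con, "raw", sz)
    # FNV-1a 64-bit-style rolling hash (no digest dependency)
    h <- 14695981039346656037
    for (chunk in split(as.integer(raw),
                        ceiling(seq_along(raw) / 65536)))
      h <- (h + sum((chunk + 1) * seq_along(chunk))) %% 2^52
    sprintf("%.0f", h)
  }
  side <- paste0(out_path, ".prov.json")
  jsonlite::write_json(list(
    artifact = basename(out_path),
    created = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("pact3d")),
    seed = seed, config = config,
    inputs = lapply(stats::setNames(inputs, basename(inputs)), hash_file)
  ), side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(side)
}

#' Reference table of system default constants
#'
#' The hardware and processing defaults used across the package: geometry,
#' acquisition, reconstruction and analysis parameters.
#'
#' @return Named list of defaults.
#' @export
system_defaults <- function() {
  list(
    hemisphere_radius_mm = 130,
    arc_span_deg = 83,
    elements_per_arc = 256,
    n_arcs = 4,
    element_pitch_mm = 0.74,
    center_frequency_MHz = 2.25,
    sampling_rate_MHz = 40,
    laser_rep_rate_Hz = 10,
    scan_span_deg = 90,
    voxel_size_mm = 0.13,
    motion_threshold_us = 0.025,
    depth_compensation_brain_per_cm = 0.81,
    depth_compensation_breast_per_cm = 0.72,
    blend_weight_filtered = 0.2,
    blend_weight_original = 0.8,
    bandpass_low_Hz = 0.008,
    bandpass_high_Hz = 0.09,
    stimulation_period_s = 24,
    functional_frame_rate_Hz = 0.5,
    calibration_iterations = 50,
    tumor_mu_a_per_cm = 0.105,
    background_mu_a_per_cm = 0.05
  )
}
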
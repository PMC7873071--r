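#' Zero-phase Butterworth bandpass of a volumetric series
#'
#' Applies a second-order Butterworth bandpass (default 0.008-0.09 Hz) to
#' every voxel time series. Filtering is zero-phase (forward-backward) by
#' default, which squares the magnitude response; a single causal pass is
#' available.
#'
#' @param series A `pact_series`.
#' @param low,high Band edges, Hz.
#' @param order Butterworth design order (default 2).
#' @param zero_phase Forward-backward filtering (default TRUE).
#' @return The filtered `pact_series` (stage `"bandpass"` appended to
#'   `processed`).
#' @export
bandpass_series <- function(series, low = 0.008, high = 0.09, order = 2,
                            zero_phase = TRUE) {
  stopifnot(inherits(series, "pact_series"))
  fs <- series$frame_rate
  if (high >= fs / 2)
    stop(sprintf("band edge %.3g Hz is at or above Nyquist (%.3g Hz)",
                 high, fs / 2), call. = FALSE)
  if (low <= 0 || low >= high)
    stop("need 0 < low < high", call. = FALSE)
  nt <- dim(series$data)[4]
  if (nt < 6 * order)
    stop("series too short for the filter order", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  d <- dim(series$data)
  x <- matrix(series$data, prod(d[1:3]), d[4])
  for (v in seq_len(nrow(x))) {
    # remove the series mean first: the band kills DC anyway, and a large
    # offset otherwise leaks in through the filter's edge transients
    mu <- mean(x[v, ])
    x[v, ] <- if (zero_phase) signal::filtfilt(bf, x[v, ] - mu)
              else as.numeric(signal::filter(bf, x[v, ] - mu))
  }
  series$data <- array(x, d)
  series$processed <- c(series$processed, "bandpass")
  series
}

#' Global signal regression
#'
#' Regresses the mask-mean time series (plus an intercept) out of every
#' voxel; returns the residual series. A constant global signal reduces to
#' intercept-only regression with a warning.
#'
#' @param series A `pact_series`.
#' @param mask Logical array; defaults to the series' brain mask.
#' @return The residual `pact_series` (stage `"gsr"` appended); the global
#'   regressor is stored in `global_signal`.
#' @export
global_signal_regression <- function(series, mask = series$mask) {
  stopifnot(inherits(series, "pact_series"))
  if (is.null(mask) || !any(mask)) stop("mask is empty", call. = FALSE)
  d <- dim(series$data)
  x <- matrix(series$data, prod(d[1:3]), d[4])
  g <- colMeans(x[as.vector(mask), , drop = FALSE])
  if (stats::sd(g) == 0) {
    warning("global signal is constant; regressing intercept only")
    X <- cbind(rep(1, d[4]))
  } else {
    X <- cbind(1, g)
  }
  beta <- solve(crossprod(X), crossprod(X, t(x)))
  res <- t(x) - X %*% beta
  series$data <- array(t(res), d)
  series$processed <- c(series$processed, "gsr")
  series$global_signal <- g
  series
}

# Region-mean time series matrix (T x R) from a series and label volume.
region_means <- function(series, labels) {
  R <- max(labels)
  d <- dim(series$data)
  x <- matrix(series$data, prod(d[1:3]), d[4])
  lab <- as.vector(labels)
  ts <- sapply(seq_len(R), function(r) colMeans(x[lab == r, , drop = FALSE]))
  ts
}

#' ROI-to-ROI functional connectivity matrix
#'
#' Averages the (processed) series over each labelled region and computes
#' Pearson correlation coefficients between all region pairs. The pipeline
#' guard requires that bandpass filtering and global signal regression have
#' been applied, in that order, before region averaging.
#'
#' @param series A `pact_series` (bandpassed + GSR).
#' @param rois A `pact_roiset` label volume; defaults to the series'
#'   labels.
#' @param method Correlation method (`"pearson"` default, `"spearman"`
#'   offered).
#' @param check Enforce the processing-order guard (default TRUE).
#' @return A `pact_connectivity`: R x R symmetric correlation matrix with
#'   unit diagonal; zero-variance regions yield `NA` entries and are listed
#'   in the `degenerate_regions` attribute.
#' @export
roi_connectivity <- function(series, rois = NULL,
                             method = c("pearson", "spearman"),
                             check = TRUE) {
  stopifnot(inherits(series, "pact_series"))
  method <- match.arg(method)
  if (check) {
    p <- series$processed
    ib <- match("bandpass", p); ig <- match("gsr", p)
    if (is.na(ib) || is.na(ig) || ib > ig)
      stop("connectivity requires bandpass filtering followed by global ",
           "signal regression before region averaging (pipeline order); ",
           "use check = FALSE to override", call. = FALSE)
  }
  labels <- if (is.null(rois)) series$labels else unclass(rois)
  ts <- region_means(series, labels)
  sds <- apply(ts, 2, stats::sd)
  degenerate <- which(sds == 0)
  C <- suppressWarnings(stats::cor(ts, method = method))
  C[degenerate, ] <- NA_real_
  C[, degenerate] <- NA_real_
  diag(C) <- 1
  nm <- attr(rois, "names") %||% paste0("R", seq_len(ncol(C)))
  dimnames(C) <- list(nm, nm)
  structure(C, degenerate_regions = degenerate,
            class = c("pact_connectivity", "matrix", "array"))
}

#' Fractional signal change per region
#'
#' Computes (mean_t - mean_baseline) / mean_baseline for each region at
#' every frame, relative to the mean over a baseline window.
#'
#' @param series A `pact_series`.
#' @param baseline_window Integer frame indices of the baseline.
#' @param rois Label volume; defaults to the series' labels.
#' @return T x R matrix of fractional changes.
#' @export
fractional_change <- function(series, baseline_window, rois = NULL) {
  stopifnot(inherits(series, "pact_series"))
  nt <- dim(series$data)[4]
  if (any(baseline_window < 1) || any(baseline_window > nt))
    stop("baseline window outside the series", call. = FALSE)
  labels <- if (is.null(rois)) series$labels else unclass(rois)
  ts <- region_means(series, labels)
  base <- colMeans(ts[baseline_window, , drop = FALSE])
  if (any(base == 0))
    stop("zero baseline mean in region(s) ",
         paste(which(base == 0), collapse = ", "), call. = FALSE)
  sweep(sweep(ts, 2, base), 2, base, "/")
}

#' Cycle-averaged (block) stimulus response
#'
#' Folds the frames of a periodic stimulation run by cycle phase and
#' averages, giving the mean and SD response per phase bin for each region.
#'
#' @param series A `pact_series`.
#' @param period_s Stimulation cycle period in seconds (default 24: 12 s on
#'   followed by 12 s rest).
#' @param n_cycles Number of cycles to average; default: as many as fit.
#' @param rois Label volume; defaults to the series' labels.
#' @return List with `mean` and `sd` (phase-bin x region matrices),
#'   `n_phase_bins` and `n_cycles`.
#' @export
block_average <- function(series, period_s = 24, n_cycles = NULL,
                          rois = NULL) {
  stopifnot(inherits(series, "pact_series"))
  fpc <- period_s * series$frame_rate
  if (abs(fpc - round(fpc)) > 1e-9)
    stop("period must be an integer number of frames (frame-aligned)",
         call. = FALSE)
  fpc <- as.integer(round(fpc))
  nt <- dim(series$data)[4]
  max_cycles <- nt %/% fpc
  if (is.null(n_cycles)) n_cycles <- max_cycles
  if (n_cycles < 1 || n_cycles > max_cycles)
    stop("series too short for ", n_cycles, " cycles of ", period_s, " s",
         call. = FALSE)
  labels <- if (is.null(rois)) series$labels else unclass(rois)
  ts <- region_means(series, labels)[seq_len(n_cycles * fpc), , drop = FALSE]
  R <- ncol(ts)
  phase <- rep(seq_len(fpc), n_cycles)
  mean_m <- matrix(0, fpc, R); sd_m <- matrix(0, fpc, R)
  for (ph in seq_len(fpc)) {
    blk <- ts[phase == ph, , drop = FALSE]
    mean_m[ph, ] <- colMeans(blk)
    sd_m[ph, ] <- apply(blk, 2, stats::sd)
  }
  list(mean = mean_m, sd = sd_m, n_phase_bins = fpc, n_cycles = n_cycles)
}
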
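#' Per-firing first-arrival profile of a sinogram
#'
#' Applies the shared first-arrival detector ([detect_first_arrival()]) to
#' every (firing, channel) trace and summarizes each firing by the median
#' arrival time across channels. Firings in which more than half of the
#' channels yield no detection are flagged low-confidence.
#'
#' @param sinogram A `pact_sinogram`.
#' @param threshold_factor Passed to [detect_first_arrival()].
#' @return A `pact_arrival_profile`: list with `first_arrival` (S x N, us,
#'   `NA` where undetected), `summary` (length-S median per firing), and
#'   `low_confidence` (logical, length S).
#' @export
first_arrival_profile <- function(sinogram, threshold_factor = 5) {
  stopifnot(inherits(sinogram, "pact_sinogram"))
  tr <- sinogram$traces
  S <- dim(tr)[1]; N <- dim(tr)[2]
  fa <- matrix(NA_real_, S, N)
  for (s in seq_len(S))
    for (n in seq_len(N))
      fa[s, n] <- detect_first_arrival(tr[s, n, ], sinogram$sampling_rate,
                                       threshold_factor, sinogram$t0)
  summ <- apply(fa, 1, stats::median, na.rm = TRUE)
  low_conf <- rowMeans(is.na(fa)) > 0.5
  summ[rowMeans(is.na(fa)) == 1] <- NA_real_
  structure(list(first_arrival = fa, summary = summ,
                 low_confidence = low_conf),
            class = "pact_arrival_profile")
}

#' Flag motion-affected firings from an arrival-time profile
#'
#' The per-firing summary arrival times are median-filtered (kernel 3),
#' then first-differenced along the firing sequence. A difference whose
#' absolute value is strictly greater than `threshold_us` marks a motion
#' event; both firings forming the jump are removed. A difference exactly
#' equal to the threshold is kept.
#'
#' @param profile A `pact_arrival_profile` (or a plain numeric vector of
#'   per-firing arrival times).
#' @param threshold_us Motion threshold in us (default 0.025, the temporal
#'   sampling step at 40 MHz).
#' @param kernel Median filter kernel size (odd, default 3).
#' @return A `pact_motion_mask`: list with `keep` (logical per firing),
#'   `threshold_us`, `kernel`, and the filtered summary.
#' @export
flag_motion <- function(profile, threshold_us = 0.025, kernel = 3) {
  if (threshold_us <= 0) stop("'threshold_us' must be positive",
                              call. = FALSE)
  if (kernel %% 2 != 1) stop("'kernel' must be odd", call. = FALSE)
  x <- if (inherits(profile, "pact_arrival_profile")) profile$summary
       else as.numeric(profile)
  S <- length(x)
  filt <- if (S >= kernel)
    as.numeric(stats::runmed(x, kernel, endrule = "keep")) else x
  keep <- rep(TRUE, S)
  if (S >= 2) {
    dd <- diff(filt)
    jump <- which(abs(dd) > threshold_us)  # strictly greater
    keep[jump] <- FALSE
    keep[jump + 1] <- FALSE
  }
  keep[is.na(x)] <- FALSE
  structure(list(keep = keep, threshold_us = threshold_us, kernel = kernel,
                 filtered_summary = filt),
            class = "pact_motion_mask")
}

#' Splice motionless segments of repeated scans into one full scan
#'
#' For each firing index the trace block is taken from the earliest scan
#' whose motion mask keeps that firing (configurable preference order).
#' All scans must share the same trajectory and trace dimensions. Periodic,
#' spatially repeatable motion (e.g., breathing) makes the kept segments
#' mutually consistent.
#'
#' @param sinograms List of `pact_sinogram` objects (>= 2).
#' @param masks List of `pact_motion_mask` (or logical vectors), one per
#'   scan.
#' @param order Preference order of scans (default: earliest first).
#' @return The merged `pact_sinogram`; `meta$splice_source` records the
#'   source scan per firing and `meta$splice_coverage` the fraction of
#'   firings covered by each scan.
#' @export
splice_scans <- function(sinograms, masks, order = seq_along(sinograms)) {
  if (length(sinograms) < 2) stop("need at least 2 scans", call. = FALSE)
  if (length(masks) != length(sinograms))
    stop("one mask per scan required", call. = FALSE)
  keeps <- lapply(masks, function(m)
    if (inherits(m, "pact_motion_mask")) m$keep else as.logical(m))
  dims <- lapply(sinograms, function(x) dim(x$traces))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("scans have differing dimensions", call. = FALSE)
  S <- dims[[1]][1]
  if (any(vapply(keeps, length, 0L) != S))
    stop("mask length must equal the number of firings", call. = FALSE)
  src <- rep(NA_integer_, S)
  for (i in order) src[is.na(src) & keeps[[i]]] <- i
  if (anyNA(src))
    stop("firing(s) kept by no scan: ",
         paste(which(is.na(src)), collapse = ", "), call. = FALSE)
  out <- sinograms[[order[1]]]
  for (s in seq_len(S))
    out$traces[s, , ] <- sinograms[[src[s]]]$traces[s, , ]
  out$meta$splice_source <- src
  out$meta$splice_coverage <- vapply(seq_along(sinograms),
                                     function(i) mean(src == i), 0)
  out
}
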
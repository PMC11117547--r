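#' Zero-phase Butterworth low-pass filtering of the force channel
#'
#' Applies the force-conditioning filter (third-order Butterworth low-pass at
#' 5 Hz by default) forward and backward, so the output has no phase lag and
#' the effective magnitude response is the single-pass response squared.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz, strictly below `fs/2`.
#' @param order filter order (>= 1) of the single-pass design.
#' @return filtered vector, same length as `x`.
#' @export
filter_force <- function(x, fs, cutoff = 5, order = 3) {
  check_filter_args(length(x), fs, cutoff, order)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Zero-phase band-pass denoising of an MMG channel
#'
#' Removes limb-motion artifact drift (below the band) and wide-band sensor
#' noise (above it) with a zero-phase Butterworth band-pass, 5--100 Hz,
#' 4th order by default. Zero-phase filtering keeps cross-correlation lags
#' between channels unshifted.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate in Hz.
#' @param band two-element band (Hz), strictly inside (0, fs/2).
#' @param order filter order of the single-pass design.
#' @return filtered vector, same length as `x`.
#' @export
denoise_mmg <- function(x, fs, band = c(5, 100), order = 4) {
  if (length(band) != 2 || band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2]) {
    stop("band must lie strictly inside (0, fs/2)", call. = FALSE)
  }
  if (length(x) <= 3 * order) stop("signal too short for filter warm-up", call. = FALSE)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

check_filter_args <- function(n, fs, cutoff, order) {
  if (any(cutoff >= fs / 2) || any(cutoff <= 0)) {
    stop("cutoff must lie strictly inside (0, fs/2)", call. = FALSE)
  }
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  if (n <= 3 * order) stop("signal too short for filter warm-up", call. = FALSE)
  invisible(TRUE)
}

#' Denoise every channel of a recording
#'
#' Convenience wrapper: band-passes all MMG channels with [denoise_mmg()] and
#' low-passes the force trace with [filter_force()].
#'
#' @param rec an `mmg_recording`.
#' @param band MMG band (Hz).
#' @param force_cutoff force low-pass cutoff (Hz).
#' @return a denoised `mmg_recording`.
#' @export
denoise_recording <- function(rec, band = c(5, 100), force_cutoff = 5) {
  stopifnot(inherits(rec, "mmg_recording"))
  band <- c(band[1], min(band[2], 0.45 * rec$fs))
  rec$channels <- lapply(rec$channels, denoise_mmg, fs = rec$fs, band = band)
  rec$force <- filter_force(rec$force, rec$fs, cutoff = force_cutoff)
  rec$meta$denoised <- TRUE
  rec
}

#' Trim unstable edges from a recording
#'
#' Deletes the transient head and tail of a trial so only the stable middle
#' portion enters the analysis; with the defaults a 60 s trial keeps its
#' central 40 s. When `head`/`tail` are `NULL` they default to 10 s per edge
#' for recordings of at least 60 s and to one sixth of the duration per edge
#' otherwise. All channels, the force trace and any stored ground-truth
#' activations are trimmed identically.
#'
#' @param rec an `mmg_recording`.
#' @param head,tail seconds to delete at the start / end, or `NULL` for the
#'   duration-dependent default.
#' @return the trimmed `mmg_recording` (fs unchanged).
#' @export
trim_edges <- function(rec, head = NULL, tail = NULL) {
  stopifnot(inherits(rec, "mmg_recording"))
  n <- length(rec$force)
  dur <- n / rec$fs
  if (is.null(head)) head <- if (dur >= 60) 10 else dur / 6
  if (is.null(tail)) tail <- if (dur >= 60) 10 else dur / 6
  if (head < 0 || tail < 0) stop("head and tail must be non-negative", call. = FALSE)
  if (head + tail >= dur) {
    stop("over-trim: head + tail must be less than the recording duration",
         call. = FALSE)
  }
  i0 <- floor(head * rec$fs) + 1L
  i1 <- n - floor(tail * rec$fs)
  keep <- i0:i1
  rec$channels <- lapply(rec$channels, function(x) x[keep])
  rec$force <- rec$force[keep]
  if (!is.null(rec$activations)) rec$activations <- rec$activations[keep, , drop = FALSE]
  rec$meta$trimmed <- c(head = head, tail = tail)
  rec
}

#' Z-score standardization (population convention)
#'
#' `zscore_fit` computes per-column means and population standard deviations
#' (divisor `n`) on the training rows; `zscore_apply` standardizes a matrix
#' with previously fitted statistics and `zscore_invert` undoes it. Fitting on
#' training rows only and applying the frozen statistics to test rows avoids
#' information leaking across the chronological split.
#'
#' @param X numeric matrix (rows = observations).
#' @param stats an object returned by `zscore_fit`.
#' @return `zscore_fit`: an object of class `scaler_stats` with elements
#'   `mean` and `sd`; `zscore_apply`/`zscore_invert`: a transformed matrix.
#' @examples
#' s <- zscore_fit(cbind(a = c(1, 2, 3)))
#' zscore_apply(cbind(a = c(1, 2, 3)), s)
#' @export
zscore_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to fit a scaler", call. = FALSE)
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2, mu)^2))   # population SD, divisor n
  bad <- which(sdev <= 0 | !is.finite(sdev))
  if (length(bad)) {
    nm <- colnames(X)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("zero-variance feature(s): ", paste(nm, collapse = ", "), call. = FALSE)
  }
  structure(list(mean = mu, sd = sdev), class = "scaler_stats")
}

#' @rdname zscore_fit
#' @export
zscore_apply <- function(X, stats) {
  stopifnot(inherits(stats, "scaler_stats"))
  X <- as.matrix(X)
  if (ncol(X) != length(stats$mean)) stop("column count mismatch", call. = FALSE)
  sweep(sweep(X, 2, stats$mean), 2, stats$sd, "/")
}

#' @rdname zscore_fit
#' @export
zscore_invert <- function(X, stats) {
  stopifnot(inherits(stats, "scaler_stats"))
  X <- as.matrix(X)
  sweep(sweep(X, 2, stats$sd, "*"), 2, stats$mean, "+")
}
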
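#' Zero-phase band-pass filter
#'
#' Band-pass filters every channel with zero-phase (forward-backward)
#' Butterworth filtering. The band is realized as a cascade of a 4th-order
#' high-pass at `lo` and a 4th-order low-pass at `hi`, each applied with
#' `signal::filtfilt`; the cascade is numerically robust for the very low
#' high-pass edge (0.1 Hz at 1000 Hz) where a single band-pass design of
#' the same order is ill-conditioned.
#'
#' @param rec A [recording()].
#' @param lo,hi Band edges in Hz, `0 < lo < hi < fs/2`.
#' @param order Butterworth order of each cascade stage.
#' @return Filtered [recording()] of identical shape.
#' @export
bandpass_filter <- function(rec, lo = 0.1, hi = 45, order = 4) {
  stopifnot(is_recording(rec))
  if (!(lo > 0 && lo < hi && hi < rec$fs / 2))
    stop("band must satisfy 0 < lo < hi < fs/2 (Nyquist = ", rec$fs / 2, " Hz)")
  hp <- signal::butter(order, lo / (rec$fs / 2), type = "high")
  lp <- signal::butter(order, hi / (rec$fs / 2), type = "low")
  data <- t(apply(rec$data, 1, function(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x))))
  recording(data, rec$fs, rec$labels)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' that at each sample the channel mean is zero.
#'
#' @param rec A [recording()] with at least 2 channels.
#' @return Re-referenced [recording()].
#' @export
average_reference <- function(rec) {
  stopifnot(is_recording(rec))
  if (nrow(rec$data) < 2)
    stop("average reference requires at least 2 channels")
  data <- sweep(rec$data, 2, colMeans(rec$data))
  recording(data, rec$fs, rec$labels)
}

#' Cut a recording into fixed-length segments
#'
#' Non-overlapping consecutive windows of `seg_len` seconds; a trailing
#' remainder shorter than one segment is discarded.
#'
#' @param rec A [recording()] at least `seg_len` seconds long.
#' @param seg_len Segment length in seconds (default 3).
#' @return An object of class `"segment_set"`: list with `segments` (list of
#'   channels x samples matrices), `seg_len`, `fs`, `labels`, `provenance`
#'   (data frame of start samples) and `rejected_count`.
#' @export
segment_recording <- function(rec, seg_len = 3) {
  stopifnot(is_recording(rec), seg_len > 0)
  n <- round(seg_len * rec$fs)
  total <- ncol(rec$data)
  if (total < n)
    stop("recording (", total / rec$fs, " s) shorter than one segment (",
         seg_len, " s)")
  n_seg <- total %/% n
  starts <- (seq_len(n_seg) - 1) * n + 1
  segments <- lapply(starts, function(s) rec$data[, s:(s + n - 1), drop = FALSE])
  structure(list(segments = segments, seg_len = seg_len, fs = rec$fs,
                 labels = rec$labels,
                 provenance = data.frame(start_sample = starts),
                 rejected_count = 0L),
            class = "segment_set")
}

#' Reject segments exceeding an amplitude threshold
#'
#' Removes every segment containing any sample whose absolute value exceeds
#' `threshold` microvolts; order of the survivors is preserved and
#' `rejected_count` is updated.
#'
#' @param segs A `"segment_set"` from [segment_recording()].
#' @param threshold Rejection threshold in uV (default 120).
#' @return The filtered `"segment_set"`.
#' @export
reject_segments <- function(segs, threshold = 120) {
  stopifnot(inherits(segs, "segment_set"), threshold > 0)
  keep <- vapply(segs$segments, function(m) all(abs(m) <= threshold), logical(1))
  segs$rejected_count <- segs$rejected_count + sum(!keep)
  segs$segments <- segs$segments[keep]
  segs$provenance <- segs$provenance[keep, , drop = FALSE]
  segs
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments of %g s (%d rejected)\n",
              length(x$segments), x$seg_len, x$rejected_count))
  invisible(x)
}

#' Robust noise-scale estimate from wavelet coefficients
#'
#' `median(|coeffs|) / constant` with the Gaussian consistency constant
#' 0.6745 (the median absolute value of a standard normal), the standard
#' robust sigma of wideband neuronal noise used to set wavelet thresholds.
#'
#' @param coeffs Non-empty numeric vector of coefficients.
#' @param constant Consistency denominator (default 0.6745).
#' @return Non-negative scalar estimate of the noise standard deviation.
#' @export
robust_sigma <- function(coeffs, constant = 0.6745) {
  if (length(coeffs) == 0) stop("`coeffs` must be non-empty")
  stats::median(abs(coeffs)) / constant
}

#' Zero wavelet coefficients exceeding a threshold
#'
#' Sets to zero every coefficient with `|w| > K`, leaving the rest
#' unchanged. Note the direction: it is the *large* coefficients -- the
#' high-energy artifact transients -- that are suppressed, the opposite of
#' classical shrinkage denoising which keeps them.
#'
#' @param coeffs Numeric vector.
#' @param K Non-negative threshold.
#' @return Thresholded vector of the same length.
#' @export
threshold_coefficients <- function(coeffs, K) {
  stopifnot(K >= 0)
  coeffs[abs(coeffs) > K] <- 0
  coeffs
}
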
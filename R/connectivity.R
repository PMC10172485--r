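# Magnitude-squared coherence via Welch auto-/cross-spectra.

#' Welch auto- and cross-spectra of a multichannel segment
#'
#' Averages tapered, overlapped periodograms (Hann taper, per-window mean
#' removal) over all channels and channel pairs on a common frequency grid.
#'
#' @param segment Channels x samples numeric matrix, or a [recording()].
#' @param fs Sampling rate in Hz (taken from the recording if one is given).
#' @param window Window length in seconds (default 1).
#' @param overlap Window overlap fraction (default 0.5).
#' @return List of class `"spectrum_set"`: `freqs` (Hz), `cross`
#'   (freqs x channels x channels complex array, autos on the diagonal),
#'   `auto` (freqs x channels real matrix), `n_windows`, and the Welch
#'   parameters.
#' @export
welch_spectra <- function(segment, fs = NULL, window = 1, overlap = 0.5) {
  if (is_recording(segment)) {
    fs <- segment$fs
    segment <- segment$data
  }
  stopifnot(!is.null(fs))
  x <- as.matrix(segment)
  nch <- nrow(x)
  n <- round(window * fs)
  if (ncol(x) < n)
    stop("segment (", ncol(x), " samples) shorter than one window (", n, ")")
  hop <- max(round(n * (1 - overlap)), 1)
  M <- (ncol(x) - n) %/% hop + 1
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
  nf <- n %/% 2 + 1
  ii <- rep(seq_len(nch), times = nch)
  jj <- rep(seq_len(nch), each = nch)
  acc <- matrix(0 + 0i, nf, nch * nch)
  for (m in seq_len(M)) {
    seg <- x[, ((m - 1) * hop + 1):((m - 1) * hop + n), drop = FALSE]
    seg <- seg - rowMeans(seg)
    Xf <- stats::mvfft(t(seg) * taper)[seq_len(nf), , drop = FALSE]
    if (nch == 1) Xf <- matrix(Xf, ncol = 1)
    acc <- acc + Xf[, ii, drop = FALSE] * Conj(Xf[, jj, drop = FALSE])
  }
  # one-sided PSD scaling (uV^2/Hz): integral over the grid approximates
  # the signal variance; the scaling cancels in coherence ratios
  acc <- acc / (M * fs * sum(taper^2))
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  acc <- acc * dbl
  cross <- array(acc, c(nf, nch, nch))
  auto <- matrix(0, nf, nch)
  for (c in seq_len(nch)) auto[, c] <- Re(cross[, c, c])
  structure(list(freqs = (seq_len(nf) - 1) * fs / n, cross = cross,
                 auto = auto, n_windows = M, window = window,
                 overlap = overlap, taper = "hann",
                 labels = rownames(x)),
            class = "spectrum_set")
}

#' Coherence spectrum of one channel pair
#'
#' Magnitude-squared coherence `C(f) = |P_xy|^2 / (P_xx * P_yy)`, defined
#' as 0 at bins where either auto-spectrum vanishes.
#'
#' @param spec A `"spectrum_set"` from [welch_spectra()].
#' @param i,j Channel indices (or labels, if the spectra carry them),
#'   `i != j`.
#' @return Numeric vector over `spec$freqs`, values in `[0, 1]`.
#' @export
coherence_spectrum <- function(spec, i, j) {
  stopifnot(inherits(spec, "spectrum_set"))
  resolve <- function(k) {
    if (is.character(k)) {
      k2 <- match(k, spec$labels)
      if (is.na(k2)) stop("unknown channel: ", k)
      k2
    } else k
  }
  i <- resolve(i); j <- resolve(j)
  if (i == j) stop("coherence requires two distinct channels")
  num <- Mod(spec$cross[, i, j])^2
  den <- spec$auto[, i] * spec$auto[, j]
  out <- ifelse(den > 0, num / den, 0)
  pmin(pmax(out, 0), 1)
}

#' Average a coherence spectrum over a frequency band
#'
#' Unweighted mean over the bins with `lo <= f <= hi` (inclusive).
#'
#' @param cspec Numeric coherence values per frequency bin.
#' @param freqs Frequency grid, Hz.
#' @param band Length-2 numeric `(lo, hi)`, `lo < hi`.
#' @return Scalar in `[0, 1]`.
#' @export
band_average <- function(cspec, freqs, band) {
  stopifnot(length(band) == 2, band[1] < band[2])
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop("band [", band[1], ", ", band[2], "] Hz contains no bins")
  mean(cspec[sel])
}

#' Band-averaged coherence adjacency matrix of a segment
#'
#' Computes the Welch spectra of a segment restricted to the requested
#' electrode labels and returns the symmetric matrix of band-averaged
#' pairwise magnitude-squared coherences with unit diagonal. At least two
#' Welch windows are required: single-window magnitude-squared coherence is
#' identically 1 and carries no information.
#'
#' @param segment Channels x samples matrix with `rownames`, or a
#'   [recording()].
#' @param fs Sampling rate, Hz (from the recording if one is given).
#' @param labels Electrode labels to use as nodes, in output order; all
#'   must be present in the segment.
#' @param band Frequency band `(lo, hi)` in Hz (default 1-45, broadband).
#' @param window,overlap Welch parameters (defaults: 1-s Hann windows, 50%
#'   overlap).
#' @return Object of class `"coherence_matrix"`: `values` (N x N), `labels`,
#'   `band`, `n_segments_averaged` (1), and the Welch parameters.
#' @export
coherence_matrix <- function(segment, fs = NULL, labels = NULL,
                             band = c(1, 45), window = 1, overlap = 0.5) {
  if (is_recording(segment)) {
    fs <- segment$fs
    if (is.null(labels)) labels <- segment$labels
    segment <- segment$data
  }
  x <- as.matrix(segment)
  if (is.null(labels)) labels <- rownames(x)
  if (is.null(labels)) stop("`labels` required when the segment is unnamed")
  if (!is.null(rownames(x))) {
    missing <- setdiff(labels, rownames(x))
    if (length(missing) > 0)
      stop("labels missing from segment: ", paste(missing, collapse = ", "))
    x <- x[labels, , drop = FALSE]
  } else if (nrow(x) != length(labels)) {
    stop("unnamed segment must have exactly one row per label")
  }
  spec <- welch_spectra(x, fs, window, overlap)
  if (spec$n_windows < 2)
    stop("need >= 2 Welch windows per segment (single-window coherence is ",
         "identically 1); shorten the window or lengthen the segment")
  sel <- spec$freqs >= band[1] & spec$freqs <= band[2]
  if (!any(sel)) stop("band contains no frequency bins")
  N <- length(labels)
  vals <- diag(1, N)
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      num <- Mod(spec$cross[sel, i, j])^2
      den <- spec$auto[sel, i] * spec$auto[sel, j]
      cf <- ifelse(den > 0, num / den, 0)
      vals[i, j] <- vals[j, i] <- min(max(mean(cf), 0), 1)
    }
  }
  dimnames(vals) <- list(labels, labels)
  structure(list(values = vals, labels = labels, band = band,
                 n_segments_averaged = 1L,
                 welch = list(window = window, overlap = overlap,
                              n_windows = spec$n_windows, taper = "hann")),
            class = "coherence_matrix")
}

validate_coherence_matrix <- function(cm, tol = 1e-8) {
  stopifnot(inherits(cm, "coherence_matrix"))
  v <- cm$values
  if (!isTRUE(all.equal(v, t(v), tolerance = tol)))
    stop("coherence matrix is not symmetric")
  if (any(abs(diag(v) - 1) > tol)) stop("coherence matrix diagonal must be 1")
  if (any(v < -tol | v > 1 + tol)) stop("coherence values must lie in [0, 1]")
  invisible(cm)
}

#' Element-wise average of coherence matrices
#'
#' Averages per-segment adjacency matrices into a subject-level network;
#' all inputs must share labels and band.
#'
#' @param matrices Non-empty list of `"coherence_matrix"` objects.
#' @return A `"coherence_matrix"` with `n_segments_averaged` equal to the
#'   total number of segments averaged.
#' @export
average_matrices <- function(matrices) {
  if (length(matrices) == 0) stop("no matrices to average")
  ref <- matrices[[1]]
  for (m in matrices) {
    stopifnot(inherits(m, "coherence_matrix"))
    if (!identical(m$labels, ref$labels)) stop("label mismatch across matrices")
    if (!isTRUE(all.equal(m$band, ref$band))) stop("band mismatch across matrices")
  }
  vals <- Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices)
  out <- ref
  out$values <- vals
  out$n_segments_averaged <- sum(vapply(matrices, `[[`, integer(1),
                                        "n_segments_averaged"))
  out
}

#' @export
print.coherence_matrix <- function(x, ...) {
  cat(sprintf("<coherence_matrix> %d nodes, band %g-%g Hz, %d segment(s)\n",
              length(x$labels), x$band[1], x$band[2], x$n_segments_averaged))
  invisible(x)
}

#' Subject-level coherence network from a segment set
#'
#' Per-segment adjacency matrices averaged element-wise, exactly in that
#' order (coherence per segment, then matrix averaging).
#'
#' @param segs A `"segment_set"` from [segment_recording()].
#' @inheritParams coherence_matrix
#' @return A `"coherence_matrix"`.
#' @export
segments_coherence <- function(segs, labels = NULL, band = c(1, 45),
                               window = 1, overlap = 0.5) {
  stopifnot(inherits(segs, "segment_set"))
  if (length(segs$segments) == 0) stop("segment set is empty")
  if (is.null(labels)) labels <- segs$labels
  mats <- lapply(segs$segments, function(m) {
    rownames(m) <- segs$labels
    coherence_matrix(m, segs$fs, labels, band, window, overlap)
  })
  average_matrices(mats)
}
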
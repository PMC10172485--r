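#' Multichannel EEG recording
#'
#' Container for one subject/task EEG trace: a channels-by-samples numeric
#' matrix in microvolts, its sampling rate, and ordered electrode labels.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of electrode names, one per row of `data`.
#' @return An object of class `"recording"`.
#' @export
recording <- function(data, fs, labels) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (length(labels) != nrow(data))
    stop("`labels` must have one entry per channel (row) of `data`")
  if (anyDuplicated(labels))
    stop("electrode labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive sampling rate in Hz")
  if (!all(is.finite(data)))
    stop("recording contains non-finite values")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = as.character(labels)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples, fs = %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

is_recording <- function(x) inherits(x, "recording")

# coerce a recording or a labeled matrix to channels x samples matrix
as_channel_matrix <- function(x) {
  if (is_recording(x)) x$data else as.matrix(x)
}

#' Duration of a recording in seconds
#' @param rec A [recording()].
#' @return Length in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs
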
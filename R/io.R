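# Plain-text serialization: recordings and adjacency matrices as CSV with
# an electrode-label header plus a JSON sidecar carrying the metadata.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a recording as delimited text
#'
#' One header row of electrode labels, one row per sample (columns =
#' channels), plus a `<path>.json` sidecar with the sampling rate.
#'
#' @param rec A [recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(is_recording(rec))
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$labels
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, labels = rec$labels,
                            n_samples = ncol(rec$data), unit = "uV"),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Validates the sidecar metadata and, when `expect_labels` is given,
#' requires every expected electrode to be present (unknown montages are
#' rejected with the canonical 21 listed).
#'
#' @param path CSV path written by [write_recording()].
#' @param expect_labels Optional labels that must all be present; the
#'   returned recording is reordered to them.
#' @return A [recording()].
#' @export
read_recording <- function(path, expect_labels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta_path <- sidecar_path(path)
  if (!file.exists(meta_path))
    stop("missing metadata sidecar (", meta_path, "); cannot determine fs")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar lacks the sampling rate `fs`")
  df <- utils::read.csv(path, check.names = FALSE)
  data <- t(as.matrix(df))
  if (!is.null(expect_labels)) {
    missing <- setdiff(expect_labels, rownames(data))
    if (length(missing) > 0)
      stop("channel(s) missing from ", path, ": ",
           paste(missing, collapse = ", "),
           "\ncanonical montage: ", paste(canonical_montage(), collapse = " "))
    data <- data[expect_labels, , drop = FALSE]
  }
  recording(data, meta$fs, rownames(data))
}

#' Write a coherence matrix as CSV plus JSON sidecar
#'
#' @param cm A `"coherence_matrix"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coherence_matrix <- function(cm, path) {
  validate_coherence_matrix(cm)
  utils::write.csv(as.data.frame(cm$values), path, row.names = TRUE)
  jsonlite::write_json(list(band = cm$band,
                            n_segments_averaged = cm$n_segments_averaged,
                            welch = cm$welch, labels = cm$labels),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a coherence matrix written by [write_coherence_matrix()]
#'
#' Invariants (symmetry, unit diagonal, `[0, 1]` range) are re-validated on
#' load.
#'
#' @param path CSV path.
#' @return A `"coherence_matrix"`.
#' @export
read_coherence_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  vals <- as.matrix(df)
  vals <- (vals + t(vals)) / 2  # remove round-trip asymmetry at print precision
  cm <- structure(list(values = vals, labels = rownames(vals),
                       band = as.numeric(meta$band),
                       n_segments_averaged = as.integer(meta$n_segments_averaged),
                       welch = meta$welch),
                  class = "coherence_matrix")
  validate_coherence_matrix(cm)
  cm
}

#' Write / read the clinical table
#'
#' @param clinical Data frame from [simulate_clinical()].
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
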
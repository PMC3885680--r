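#' Multichannel recording container
#'
#' A `recording` holds a channels x time matrix of scalp (or subdural)
#' potentials in microvolts together with its sampling rate, channel labels,
#' and the current reference scheme.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param fs sampling rate in Hz (250 and 1000 are the supported native
#'   rates; other positive values are accepted).
#' @param labels character vector of unique channel names; defaults to
#'   `ch01 ...`.
#' @param reference `"original"` or `"CAR"` (common average reference).
#' @return An object of class `recording`.
#' @export
recording <- function(samples, fs, labels = NULL,
                      reference = c("original", "CAR")) {
  reference <- match.arg(reference)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric channels x time matrix")
  if (!all(is.finite(samples)))
    stop("`samples` contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  fs <- as.numeric(fs)
  n_ch <- nrow(samples)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(n_ch))
  if (length(labels) != n_ch || anyDuplicated(labels))
    stop("`labels` must be unique and match the number of channels")
  structure(list(samples = samples, fs = fs, labels = as.character(labels),
                 reference = reference),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s), ref=%s\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, x$reference))
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$samples)

#' Write / read a recording as a delimited matrix plus JSON header
#'
#' The sample matrix is stored as a tab-separated text file (one row per
#' channel) and the metadata (`fs`, `labels`, `units`, `reference`) as a JSON
#' sidecar `<path>.json`.
#'
#' @param x a [recording()].
#' @param path file path for the sample matrix.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [recording()].
#' @export
write_recording <- function(x, path) {
  stopifnot(inherits(x, "recording"))
  write.table(x$samples, path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  hdr <- list(fs = x$fs, labels = x$labels, units = "uV",
              reference = x$reference)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  recording(m, fs = hdr$fs, labels = hdr$labels, reference = hdr$reference)
}
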